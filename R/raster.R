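#' Regular geographic grid specification
#'
#' A north-up regular grid in geographic (longitude/latitude) coordinates.
#' Pixel (1, 1) is the north-west corner. A point belongs to the pixel whose
#' half-open cell \eqn{[x, x + \Delta) \times (y - \Delta, y]} contains it,
#' where \eqn{(x, y)} is the pixel's north-west corner and \eqn{\Delta} the
#' cell size in degrees.
#'
#' @param nrow,ncol Grid dimensions.
#' @param xll,yll Longitude/latitude of the lower-left corner of the grid.
#' @param cellsize Pixel size in decimal degrees (square pixels).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(nrow, ncol, xll, yll, cellsize) {
  stopifnot(nrow >= 1, ncol >= 1, cellsize > 0)
  structure(
    list(nrow = as.integer(nrow), ncol = as.integer(ncol),
         xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize)),
    class = "grid_spec")
}

#' @export
#' @method print grid_spec
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d pixels of %g deg, origin (%g, %g)\n",
              x$nrow, x$ncol, x$cellsize, x$xll, x$yll))
  invisible(x)
}

grid_ytop <- function(grid) grid$yll + grid$nrow * grid$cellsize
grid_xmax <- function(grid) grid$xll + grid$ncol * grid$cellsize

#' Pixel-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with `lon` (length `ncol`, west to east) and `lat`
#'   (length `nrow`, north to south), matching matrix row/column order.
#' @export
cell_centers <- function(grid) {
  list(
    lon = grid$xll + (seq_len(grid$ncol) - 0.5) * grid$cellsize,
    lat = grid_ytop(grid) - (seq_len(grid$nrow) - 0.5) * grid$cellsize)
}

#' Map points to grid pixels
#'
#' Uses the package's fixed convention: half-open cells
#' \eqn{[x, x+\Delta) \times (y-\Delta, y]} anchored at each pixel's
#' north-west corner, so a point on a cell's northern edge belongs to that
#' cell and a point on its eastern edge to the next cell east.
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Numeric vectors of coordinates.
#' @return Data frame with integer columns `row`, `col` (NA outside grid).
#' @export
point_to_cell <- function(grid, lon, lat) {
  col <- floor((lon - grid$xll) / grid$cellsize) + 1L
  # flooring the offset from the north edge places a point exactly on an
  # internal cell-top edge in that cell, and lat == ytop in row 1, which
  # is precisely the half-open (y - delta, y] convention
  row <- floor((grid_ytop(grid) - lat) / grid$cellsize) + 1L
  bad <- is.na(row) | is.na(col) | row < 1L | row > grid$nrow |
    col < 1L | col > grid$ncol
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  data.frame(row = row, col = col)
}

# vector index of a (row, col) cell in the column-major field vector
cell_index <- function(grid, row, col) (col - 1L) * grid$nrow + row

RASTER_KINDS <- c("ntl", "lulc", "iap", "pia", "population",
                  "probability", "binary", "unknown")

#' Construct a raster layer
#'
#' The in-memory raster container: a matrix of values (row 1 = northernmost
#' row) on a [grid_spec()], with missing pixels stored as `NA` and a declared
#' semantic kind. Kind-specific invariants are enforced: `ntl` values are
#' integers in 0-63, `lulc` categories in 1-7, `iap`/`pia`/`probability`
#' in \[0, 1\], `population` non-negative, `binary` in \{0, 1\}.
#'
#' @param values Numeric matrix, dimensions matching `grid`.
#' @param grid A [grid_spec()].
#' @param kind One of `"ntl"`, `"lulc"`, `"iap"`, `"pia"`, `"population"`,
#'   `"probability"`, `"binary"`, `"unknown"`.
#' @param nodata Sentinel written for `NA` pixels on file output.
#' @param crs Coordinate reference system label; must be geographic.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid, kind = "unknown", nodata = -9999,
                         crs = "EPSG:4326") {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"))
  if (nrow(values) != grid$nrow || ncol(values) != grid$ncol) {
    stop("values dimensions do not match grid")
  }
  kind <- match.arg(kind, RASTER_KINDS)
  v <- values[!is.na(values)]
  ok <- switch(kind,
    ntl = all(v == round(v)) && all(v >= 0 & v <= 63),
    lulc = all(v %in% 1:7),
    iap = ,
    pia = ,
    probability = all(v >= 0 & v <= 1),
    population = all(v >= 0),
    binary = all(v %in% c(0, 1)),
    TRUE)
  if (!ok) stop(sprintf("values violate the '%s' kind invariant", kind))
  structure(
    list(values = values, grid = grid, kind = kind,
         nodata = nodata, crs = crs),
    class = "raster_layer")
}

#' @export
#' @method print raster_layer
print.raster_layer <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_layer [%s]: %d x %d, %d valid pixels",
              x$kind, x$grid$nrow, x$grid$ncol, length(v)))
  if (length(v)) cat(sprintf(", range [%g, %g]", min(v), max(v)))
  cat("\n")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-9) {
  ga <- if (inherits(a, "raster_layer")) a$grid else a
  gb <- if (inherits(b, "raster_layer")) b$grid else b
  ga$nrow == gb$nrow && ga$ncol == gb$ncol &&
    abs(ga$xll - gb$xll) < tol && abs(ga$yll - gb$yll) < tol &&
    abs(ga$cellsize - gb$cellsize) < tol
}

GEOGRAPHIC_CRS <- c("EPSG:4326", "WGS84", "OGC:CRS84", "lonlat", "longlat")

#' Read a raster from an ESRI ASCII grid file
#'
#' Reads the plain-text `.asc` format (header of six `key value` lines
#' followed by `nrows` rows of values, north to south). A JSON sidecar
#' `<path>.json`, if present, supplies the semantic kind and CRS; an explicit
#' `kind` argument overrides it. Projected coordinate systems are rejected.
#'
#' @param path Path to the `.asc` file.
#' @param kind Optional kind override (see [raster_layer()]).
#' @return A [raster_layer()].
#' @export
read_raster <- function(path, kind = NULL) {
  if (!file.exists(path)) stop("raster file not found: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2) stop("malformed ASCII grid header in ", path)
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
            "nodata_value")
  if (!all(need %in% names(hdr))) {
    stop("ASCII grid header missing fields: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  }
  vals <- scan(path, skip = 6L, quiet = TRUE)
  if (length(vals) != hdr$ncols * hdr$nrows) {
    stop(sprintf("expected %d values, found %d in %s",
                 hdr$ncols * hdr$nrows, length(vals), path))
  }
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  m[m == hdr$nodata_value] <- NA_real_
  crs <- "EPSG:4326"
  side_kind <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$crs)) crs <- meta$crs
    if (!is.null(meta$kind)) side_kind <- meta$kind
  }
  if (!(crs %in% GEOGRAPHIC_CRS)) {
    stop("raster is not in a geographic lon/lat coordinate system (CRS: ",
         crs, ")")
  }
  kind <- if (!is.null(kind)) kind else if (!is.null(side_kind)) side_kind
    else "unknown"
  grid <- grid_spec(hdr$nrows, hdr$ncols, hdr$xllcorner, hdr$yllcorner,
                    hdr$cellsize)
  raster_layer(m, grid, kind = kind, nodata = hdr$nodata_value, crs = crs)
}

#' Write a raster to an ESRI ASCII grid file
#'
#' Values are written at full (17 significant digit) precision with `NA`
#' pixels as the layer's nodata sentinel; a JSON sidecar `<path>.json`
#' records the kind tag and CRS so [read_raster()] can restore them.
#'
#' @param layer A [raster_layer()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_raster <- function(layer, path) {
  stopifnot(inherits(layer, "raster_layer"))
  g <- layer$grid
  m <- layer$values
  m[is.na(m)] <- layer$nodata
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write raster to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$ncol),
    sprintf("nrows %d", g$nrow),
    sprintf("xllcorner %.17g", g$xll),
    sprintf("yllcorner %.17g", g$yll),
    sprintf("cellsize %.17g", g$cellsize),
    sprintf("NODATA_value %.17g", layer$nodata)), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r),
                                           collapse = " ")), con)
  jsonlite::write_json(
    list(kind = layer$kind, crs = layer$crs, nodata = layer$nodata),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
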
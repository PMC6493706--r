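test_that("raster write/read roundtrip is the identity for every kind", {
  g <- grid_spec(6, 8, 12.5, -3.25, 0.045)
  cases <- list(
    ntl = matrix(sample(0:63, 48, replace = TRUE), 6, 8),
    lulc = matrix(sample(1:7, 48, replace = TRUE), 6, 8),
    probability = matrix(runif(48), 6, 8),
    population = matrix(rexp(48, 1e-3), 6, 8))
  for (kind in names(cases)) {
    vals <- cases[[kind]]
    vals[2, 3] <- NA
    lay <- raster_layer(vals, g, kind = kind)
    path <- file.path(tempdir(), paste0("rt_", kind, ".asc"))
    write_raster(lay, path)
    back <- read_raster(path)
    expect_identical(back$kind, kind)
    expect_equal(back$values, lay$values)
    expect_equal(back$grid, g)
    expect_equal(back$nodata, lay$nodata)
  }
})

test_that("an all-nodata raster reads back with zero valid pixels", {
  g <- grid_spec(4, 4, 0, 0, 0.045)
  lay <- raster_layer(matrix(NA_real_, 4, 4), g, kind = "probability")
  path <- file.path(tempdir(), "allna.asc")
  write_raster(lay, path)
  back <- read_raster(path)
  expect_identical(sum(!is.na(back$values)), 0L)
})

test_that("malformed or unsupported raster inputs error clearly", {
  expect_error(read_raster(file.path(tempdir(), "nope.asc")), "not found")
  bad <- file.path(tempdir(), "bad.asc")
  writeLines(c("ncols 2 2", "junk"), bad)
  expect_error(read_raster(bad), "header")
  # projected CRS declared in the sidecar is rejected by name
  g <- grid_spec(3, 3, 0, 0, 0.045)
  lay <- raster_layer(matrix(0.5, 3, 3), g, kind = "probability")
  path <- file.path(tempdir(), "proj.asc")
  write_raster(lay, path)
  jsonlite::write_json(list(kind = "probability", crs = "EPSG:32633"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(read_raster(path), "EPSG:32633")
})

test_that("kind invariants are enforced at construction", {
  g <- grid_spec(2, 2, 0, 0, 0.045)
  expect_error(raster_layer(matrix(64, 2, 2), g, kind = "ntl"),
               "invariant")
  expect_error(raster_layer(matrix(2.5, 2, 2), g, kind = "ntl"),
               "invariant")
  expect_error(raster_layer(matrix(8, 2, 2), g, kind = "lulc"),
               "invariant")
  expect_error(raster_layer(matrix(1.2, 2, 2), g, kind = "probability"),
               "invariant")
  expect_error(raster_layer(matrix(-1, 2, 2), g, kind = "population"),
               "invariant")
  expect_silent(raster_layer(matrix(0.5, 2, 2), g, kind = "pia"))
})

test_that("points map to pixels by the half-open north-west convention", {
  g <- grid_spec(4, 4, 10, 0, 0.5)  # lat 0..2, lon 10..12
  # pixel (1,1) is the NW corner cell
  expect_equal(point_to_cell(g, 10.0, 2.0), data.frame(row = 1L, col = 1L))
  # interior point
  expect_equal(point_to_cell(g, 10.7, 0.2), data.frame(row = 4L, col = 2L))
  # lon on a cell's east edge belongs to the next cell east
  expect_equal(point_to_cell(g, 10.5, 1.9)$col, 2L)
  # lat on an internal cell top edge belongs to that cell (half-open in y)
  expect_equal(point_to_cell(g, 10.1, 1.5)$row, 2L)
  # outside the grid
  expect_true(is.na(point_to_cell(g, 9.9, 1.0)$row))
  expect_true(is.na(point_to_cell(g, 10.1, 2.1)$row))
})

test_that("cluster CSV roundtrip preserves fields and ordering", {
  df <- data.frame(
    cluster_id = c("a1", "a2", "a3"), lon = c(30.1, 30.5, 31.0),
    lat = c(-0.5, 0.2, 0.9), year = c(2000L, 2005L, 2013L),
    country = c("R1", "R1", "R2"), urban = c(TRUE, FALSE, FALSE),
    n_households = c(24L, 24L, 3L), n_electrified = c(24L, 0L, 2L),
    displaced = c(FALSE, FALSE, TRUE))
  path <- file.path(tempdir(), "clusters.csv")
  write_clusters(df, path)
  back <- read_clusters(path)
  expect_equal(as.data.frame(back), df, ignore_attr = TRUE)
})

test_that("invalid cluster rows are rejected with their row numbers", {
  path <- file.path(tempdir(), "badclusters.csv")
  writeLines(c(
    "cluster_id,lon,lat,year,country,urban,n_households,n_electrified",
    "c1,30.0,0.0,2005,R1,0,24,24",
    "c2,30.1,0.1,2005,R1,0,24,25",
    "c3,xx,0.2,2005,R1,1,10,5"), path)
  err <- tryCatch(read_clusters(path), error = conditionMessage)
  expect_match(err, "rows 2")
  expect_match(err, "rows 3")
  expect_match(err, "non-numeric coordinates")
  # a full cluster with every household electrified is fine
  writeLines(c(
    "cluster_id,lon,lat,year,country,urban,n_households,n_electrified",
    "c1,30.0,0.0,2005,R1,0,24,24"), path)
  expect_silent(read_clusters(path))
  # year outside the study window
  writeLines(c(
    "cluster_id,lon,lat,year,country,urban,n_households,n_electrified",
    "c1,30.0,0.0,1995,R1,0,24,4"), path)
  expect_error(read_clusters(path), "study window")
})

test_that("a header-only cluster file yields an empty table with warning", {
  path <- file.path(tempdir(), "empty.csv")
  writeLines(
    "cluster_id,lon,lat,year,country,urban,n_households,n_electrified",
    path)
  expect_warning(out <- read_clusters(path), "no rows")
  expect_identical(nrow(out), 0L)
})
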
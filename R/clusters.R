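#' Read survey clusters from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns `cluster_id`,
#' `lon`, `lat`, `year`, `country`, `urban`, `n_households`,
#' `n_electrified` and optionally `displaced` (booleans coded 0/1).
#' Each row is validated: coordinates numeric, `0 <= n_electrified <=
#' n_households`, `n_households >= 1`, year inside the study window.
#' Violations are rejected row-wise with an error naming the offending rows.
#'
#' @param path CSV path.
#' @param year_range Inclusive study window, default `c(2000, 2013)`.
#' @return Data frame of clusters (one row per cluster) with logical
#'   `urban` and `displaced` columns.
#' @export
read_clusters <- function(path, year_range = c(2000, 2013)) {
  if (!file.exists(path)) stop("cluster file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(cluster_id = "character"))
  need <- c("cluster_id", "lon", "lat", "year", "country", "urban",
            "n_households", "n_electrified")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cluster CSV missing columns: ",
                         paste(miss, collapse = ", "))
  if (!"displaced" %in% names(df)) df$displaced <- rep(0L, nrow(df))
  if (nrow(df) == 0) {
    warning("cluster file has a header but no rows: ", path)
    df$urban <- logical(0); df$displaced <- logical(0)
    return(validate_clusters(df, year_range))
  }
  problems <- character(0)
  add <- function(rows, what) {
    if (any(rows)) problems <<- c(problems, sprintf(
      "%s (rows %s)", what, paste(which(rows), collapse = ", ")))
  }
  suppressWarnings({
    lon <- as.numeric(df$lon); lat <- as.numeric(df$lat)
    n <- as.numeric(df$n_households); k <- as.numeric(df$n_electrified)
    yr <- as.numeric(df$year)
  })
  add(is.na(lon) | is.na(lat), "non-numeric coordinates")
  add(!is.na(n) & !is.na(k) & k > n,
      "n_electrified exceeds n_households")
  add(is.na(n) | n < 1 | n != round(n), "invalid n_households")
  add(!is.na(k) & (k < 0 | k != round(k)), "invalid n_electrified")
  add(is.na(yr) | yr < year_range[1] | yr > year_range[2],
      sprintf("year outside study window %d-%d", year_range[1],
              year_range[2]))
  if (length(problems)) {
    stop("invalid cluster rows in ", path, ":\n  ",
         paste(problems, collapse = "\n  "))
  }
  df$lon <- lon; df$lat <- lat
  df$year <- as.integer(yr)
  df$n_households <- as.integer(n)
  df$n_electrified <- as.integer(k)
  df$urban <- as.logical(as.integer(df$urban))
  df$displaced <- as.logical(as.integer(df$displaced))
  validate_clusters(df, year_range)
}

validate_clusters <- function(df, year_range = c(2000, 2013)) {
  attr(df, "year_range") <- year_range
  class(df) <- c("survey_clusters", "data.frame")
  df
}

#' Write survey clusters to CSV
#'
#' Inverse of [read_clusters()]; booleans are written as 0/1.
#'
#' @param clusters Cluster data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_clusters <- function(clusters, path) {
  out <- as.data.frame(clusters)
  out$urban <- as.integer(out$urban)
  out$displaced <- as.integer(out$displaced)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
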
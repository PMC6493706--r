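#' Interpolate quinquennial population rasters to annual
#'
#' Between consecutive snapshots at years `t0` and `t0 + 5`, each pixel
#' grows geometrically: \eqn{P(t_0 + j) = P(t_0) r^{j/5}} with
#' \eqn{r = P(t_0+5)/P(t_0)}. Pixels with \eqn{P(t_0) = 0} and
#' \eqn{P(t_0+5) > 0}, for which geometric growth is undefined, are
#' interpolated linearly (their count is reported in a message). Snapshot
#' years are returned unchanged.
#'
#' @param quinquennial Named list (by year) of aligned `population`
#'   rasters at two or more snapshot years.
#' @return Named list of `population` rasters covering every year from the
#'   first to the last snapshot.
#' @export
interpolate_population_annual <- function(quinquennial) {
  years <- as.integer(names(quinquennial))
  if (length(years) < 2) stop("need at least 2 quinquennial rasters")
  if (is.unsorted(years)) stop("quinquennial years must be sorted")
  g <- quinquennial[[1]]$grid
  for (lay in quinquennial) {
    if (!same_grid(lay, g)) stop("population rasters are misaligned")
    if (any(lay$values[!is.na(lay$values)] < 0)) {
      stop("negative population values")
    }
  }
  out <- list()
  n_linear <- 0L
  for (q in seq_len(length(years) - 1)) {
    t0 <- years[q]; t1 <- years[q + 1]
    gap <- t1 - t0
    P0 <- quinquennial[[as.character(t0)]]$values
    P1 <- quinquennial[[as.character(t1)]]$values
    out[[as.character(t0)]] <- quinquennial[[as.character(t0)]]
    lin <- !is.na(P0) & !is.na(P1) & P0 == 0 & P1 > 0
    n_linear <- n_linear + sum(lin)
    r <- P1 / P0
    for (j in seq_len(gap - 1)) {
      Pj <- P0 * r^(j / gap)
      Pj[lin] <- P1[lin] * j / gap
      Pj[!is.na(P0) & P0 == 0 & !lin] <- 0
      out[[as.character(t0 + j)]] <- raster_layer(Pj, g,
                                                  kind = "population")
    }
  }
  out[[as.character(years[length(years)])]] <-
    quinquennial[[as.character(years[length(years)])]]
  if (n_linear > 0) {
    message(n_linear,
            " zero-to-positive pixel transition(s) interpolated linearly")
  }
  out
}

#' Population share in likely-access pixels
#'
#' `100 * sum(pop over pixels with p > threshold) / sum(pop over all valid
#' pixels in the region)`, with the strict inequality matching the
#' classification rule.
#'
#' @param prob A `probability` [raster_layer()].
#' @param pop An aligned `population` [raster_layer()].
#' @param region_mask Optional aligned binary raster selecting the region
#'   (`NULL` = whole grid).
#' @param threshold Probability threshold, default 0.5.
#' @return Share in percent.
#' @export
population_share_above_threshold <- function(prob, pop,
                                             region_mask = NULL,
                                             threshold = 0.5) {
  stopifnot(inherits(prob, "raster_layer"), inherits(pop, "raster_layer"))
  if (!same_grid(prob, pop)) stop("probability and population misaligned")
  sel <- !is.na(prob$values) & !is.na(pop$values)
  if (!is.null(region_mask)) {
    if (!same_grid(region_mask, pop)) stop("region mask misaligned")
    sel <- sel & !is.na(region_mask$values) & region_mask$values == 1
  }
  total <- sum(pop$values[sel])
  if (total <= 0) stop("zero total population in region")
  above <- sel & prob$values > threshold
  100 * sum(pop$values[above]) / total
}

#' Build a population-share trend table
#'
#' One row per (region, year) plus an `"all"` row per year: total
#' population, population in pixels with `p > threshold`, and the share in
#' percent. Regions with zero population get `NA` shares and a flag.
#'
#' @param prob_by_year Named list (by year) of probability rasters.
#' @param pop_by_year Named list (by year) of aligned population rasters
#'   covering the same years.
#' @param region_masks Named list of binary region rasters (may be
#'   `NULL` for no regional breakdown).
#' @param threshold Probability threshold, default 0.5.
#' @return Data frame with columns `region`, `year`, `pop_total`,
#'   `pop_above`, `share_pct`, `flagged`.
#' @export
build_trend_table <- function(prob_by_year, pop_by_year,
                              region_masks = NULL, threshold = 0.5) {
  years <- names(prob_by_year)
  miss <- setdiff(years, names(pop_by_year))
  if (length(miss)) stop("population rasters missing for year(s): ",
                         paste(miss, collapse = ", "))
  regions <- c(list(all = NULL), region_masks)
  rows <- list()
  for (yr in years) {
    prob <- prob_by_year[[yr]]
    pop <- pop_by_year[[yr]]
    for (rn in names(regions)) {
      mask <- regions[[rn]]
      sel <- !is.na(prob$values) & !is.na(pop$values)
      if (!is.null(mask)) {
        sel <- sel & !is.na(mask$values) & mask$values == 1
      }
      tot <- sum(pop$values[sel])
      above <- sum(pop$values[sel & prob$values > threshold])
      rows[[length(rows) + 1L]] <- data.frame(
        region = rn, year = as.integer(yr), pop_total = tot,
        pop_above = above,
        share_pct = if (tot > 0) 100 * above / tot else NA_real_,
        flagged = tot <= 0)
    }
  }
  do.call(rbind, rows)
}
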
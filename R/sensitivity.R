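#' Displacement sensitivity experiment
#'
#' Quantifies, on synthetic ground truth, how DHS-style coordinate jitter
#' degrades the fitted surfaces. Per replicate: a landscape, covariate
#' stack, truth surface and cluster sample are generated; the model is
#' fitted once to the true coordinates and once to displaced coordinates
#' (covariates re-extracted at the displaced locations, as an analyst of
#' displaced data would); both fits predict every study year and the sum
#' of squared errors (SSE) against the true probability surface over all
#' valid pixels is compared:
#' `sse_increment_pct = 100 * (SSE_displaced - SSE_clean) / SSE_clean`.
#'
#' @param sim_config A [sim_config()]; its seed is re-derived per
#'   replicate.
#' @param rule A [displacement_rule()].
#' @param spec The [model_spec()] to fit (default M3, the selected model).
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Integer base seed.
#' @param buffer_km Covariate extraction buffer, default 5 km.
#' @param control Passed to [fit_model()].
#' @return An object of class `sensitivity_result`: per-replicate SSEs and
#'   increments, their mean and spread, per-parameter clean/displaced
#'   estimates with standard deviations, true values, hyperparameter
#'   estimates, the seeds used and the count of failed replicates.
#' @export
run_displacement_experiment <- function(sim_config,
                                        rule = displacement_rule(),
                                        spec = model_spec("M3"),
                                        n_replicates = 20, seed = 1,
                                        buffer_km = 5,
                                        control = list()) {
  stopifnot(n_replicates >= 1)
  reps <- list()
  failed <- 0L
  seeds <- seed + 1000L * seq_len(n_replicates)
  for (r in seq_len(n_replicates)) {
    res <- tryCatch(
      run_displacement_replicate(sim_config, rule, spec, seeds[r],
                                 buffer_km, control),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- failed + 1L
      warning("replicate ", r, " failed: ", conditionMessage(res))
    } else {
      reps[[length(reps) + 1L]] <- res
    }
  }
  if (!length(reps)) stop("all replicates failed")
  inc <- vapply(reps, `[[`, numeric(1), "sse_increment_pct")
  param_names <- names(reps[[1]]$beta_hat_clean)
  collect <- function(fld) {
    do.call(rbind, lapply(reps, function(x) x[[fld]][param_names]))
  }
  structure(list(
    n_replicates = n_replicates, n_used = length(reps),
    n_failed = failed, seeds = seeds,
    beta_true = reps[[1]]$beta_true[param_names],
    sse_clean = vapply(reps, `[[`, numeric(1), "sse_clean"),
    sse_displaced = vapply(reps, `[[`, numeric(1), "sse_displaced"),
    sse_increment_pct = inc,
    mean_increment_pct = mean(inc),
    sd_increment_pct = if (length(inc) > 1) sd(inc) else NA_real_,
    beta_hat_clean = collect("beta_hat_clean"),
    beta_sd_clean = collect("beta_sd_clean"),
    beta_hat_displaced = collect("beta_hat_displaced"),
    beta_sd_displaced = collect("beta_sd_displaced"),
    hyper_hat_clean = do.call(rbind, lapply(reps, `[[`, "hyper_clean")),
    hyper_hat_displaced = do.call(rbind,
                                  lapply(reps, `[[`, "hyper_displaced")),
    rule = rule, variant = spec$variant),
    class = "sensitivity_result")
}

run_displacement_replicate <- function(base_config, rule, spec, rep_seed,
                                       buffer_km, control) {
  cfg <- base_config
  cfg$seed <- rep_seed
  land <- generate_landscape(cfg)
  stack <- build_covariates(land)
  truth <- generate_truth_surface(cfg, stack)
  clusters <- sample_clusters(truth, stack, cfg)
  displaced <- displace_clusters(clusters, rule, seed = rep_seed + 7L)
  obs_clean <- extract_buffer_covariates(stack, clusters, buffer_km)
  obs_disp <- extract_buffer_covariates(stack, displaced, buffer_km)
  # jitter can push near-edge points off the modelling domain; an analyst
  # only keeps observations inside it
  inside <- function(o) o[!is.na(point_to_cell(cfg$grid, o$lon,
                                               o$lat)$row), ,
                          drop = FALSE]
  obs_clean <- inside(obs_clean)
  obs_disp <- inside(obs_disp)
  fit_clean <- fit_model(spec, obs_clean, grid = cfg$grid,
                         field_sd = FALSE, control = control)
  fit_disp <- fit_model(spec, obs_disp, grid = cfg$grid,
                        field_sd = FALSE, control = control)
  sse <- function(fit) {
    tot <- 0
    for (t in cfg$years) {
      pred <- predict_surface(fit, stack, t)
      pt <- truth$prob[[as.character(t)]]$values
      ok <- !is.na(pred$values) & !is.na(pt)
      tot <- tot + sum((pred$values[ok] - pt[ok])^2)
    }
    tot
  }
  sse_clean <- sse(fit_clean)
  sse_disp <- sse(fit_disp)
  list(
    beta_true = cfg$beta_true,
    beta_hat_clean = fit_clean$beta_mean,
    beta_sd_clean = fit_clean$beta_sd,
    beta_hat_displaced = fit_disp$beta_mean,
    beta_sd_displaced = fit_disp$beta_sd,
    hyper_clean = c(rho = fit_clean$rho_hat,
                    sigma_s = fit_clean$sigma_s_hat),
    hyper_displaced = c(rho = fit_disp$rho_hat,
                        sigma_s = fit_disp$sigma_s_hat),
    sse_clean = sse_clean, sse_displaced = sse_disp,
    sse_increment_pct = 100 * (sse_disp - sse_clean) / sse_clean)
}

#' @export
#' @method print sensitivity_result
print.sensitivity_result <- function(x, ...) {
  cat(sprintf(
    "Displacement sensitivity (%s, %d/%d replicates used)\n",
    x$variant, x$n_used, x$n_replicates))
  cat(sprintf("mean SSE increment: %.2f%% (sd %.2f%%)\n",
              x$mean_increment_pct, x$sd_increment_pct))
  invisible(x)
}

#' Compare clean and displaced parameter estimates
#'
#' Per parameter, the mean estimate under clean and displaced fits, the
#' fraction of replicates in which the two 95% intervals overlap, and a
#' flag for parameters whose intervals are disjoint in most replicates.
#'
#' @param result A [run_displacement_experiment()] result.
#' @return Data frame with one row per fixed effect.
#' @export
compare_estimates <- function(result) {
  stopifnot(inherits(result, "sensitivity_result"))
  pn <- colnames(result$beta_hat_clean)
  rows <- lapply(seq_along(pn), function(j) {
    lc <- result$beta_hat_clean[, j] - 1.96 * result$beta_sd_clean[, j]
    uc <- result$beta_hat_clean[, j] + 1.96 * result$beta_sd_clean[, j]
    ld <- result$beta_hat_displaced[, j] -
      1.96 * result$beta_sd_displaced[, j]
    ud <- result$beta_hat_displaced[, j] +
      1.96 * result$beta_sd_displaced[, j]
    overlap <- lc <= ud & ld <= uc
    # a replicate whose design lacked this parameter contributes NA
    data.frame(
      parameter = pn[j],
      true = unname(result$beta_true[pn[j]]),
      estimate_clean = mean(result$beta_hat_clean[, j], na.rm = TRUE),
      estimate_displaced = mean(result$beta_hat_displaced[, j],
                                na.rm = TRUE),
      overlap_fraction = mean(overlap, na.rm = TRUE),
      disjoint = mean(overlap, na.rm = TRUE) < 0.5)
  })
  do.call(rbind, rows)
}
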
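#!/usr/bin/env Rscript
# Stage 4: held-out validation with synthetic classes.
#
# Refits the chosen model on the training set, predicts the probability
# of access at the held-out validation clusters, thresholds at 0.5 and
# compares against synthetic Bernoulli(k/n) class instances — the
# confusion-matrix / accuracy / precision / sensitivity recipe.

suppressPackageStartupMessages(library(elecmbg))

raster_dir <- "scratch/analysis"
manifest <- jsonlite::read_json("results/simulation_manifest.json",
                                simplifyVector = TRUE)
g <- do.call(grid_spec, as.list(manifest$grid))
chosen <- jsonlite::read_json("results/chosen_model.json",
                              simplifyVector = TRUE)$chosen
obs <- read.csv("scratch/analysis/observations.csv",
                colClasses = c(cluster_id = "character"))

layers <- list()
for (t in manifest$years) {
  yr <- as.character(t)
  layers[[yr]] <- list(
    ntl = read_raster(file.path(raster_dir,
                                sprintf("ntl_%s.asc", yr))),
    lulc = read_raster(file.path(raster_dir,
                                 sprintf("lulc5km_%s.asc", yr))),
    iap = read_raster(file.path(raster_dir,
                                sprintf("iap_%s.asc", yr))),
    pia = read_raster(file.path(raster_dir,
                                sprintf("pia_%s.asc", yr))))
}
stack <- covariate_stack(g, layers)

sp <- split_train_validation(obs, train_fraction = 0.7, seed = 2026)
fit <- fit_model(model_spec(chosen), sp$train, grid = g,
                 field_sd = FALSE)

val <- sp$validation
pred_p <- numeric(nrow(val))
for (t in unique(val$year)) {
  surf <- predict_surface(fit, stack, t)
  sel <- val$year == t
  cells <- point_to_cell(g, val$lon[sel], val$lat[sel])
  pred_p[sel] <- surf$values[cbind(cells$row, cells$col)]
}
ok <- !is.na(pred_p)
if (any(!ok)) {
  message(sum(!ok), " validation cluster(s) without a prediction dropped")
}
val <- val[ok, , drop = FALSE]
pred_class <- as.integer(pred_p[ok] > 0.5)

val_clusters <- data.frame(cluster_id = val$cluster_id,
                           n_households = val$n,
                           n_electrified = val$k)
report <- validate_predictions(pred_class, val_clusters,
                               draws_per_cluster = 1, seed = 2026)
print(report)
jsonlite::write_json(
  list(tn = report$matrix$tn, fn = report$matrix$fn,
       fp = report$matrix$fp, tp = report$matrix$tp,
       accuracy = report$accuracy, precision = report$precision,
       sensitivity = report$sensitivity,
       n_evaluated = report$n_evaluated),
  "results/validation_report.json", auto_unbox = TRUE, digits = NA)
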
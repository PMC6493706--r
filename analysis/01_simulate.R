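#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study region.
#
# Generates the landscape (annual nighttime lights, high-resolution land
# cover), the ground-truth probability-of-access surfaces, a cluster-level
# household survey and its DHS-displaced twin. Rasters and per-cluster
# tables go to scratch/analysis/ (bulky, regenerable); the true-parameter
# manifest goes to results/.

suppressPackageStartupMessages(library(elecmbg))

raster_dir <- "scratch/analysis"
dir.create(raster_dir, recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(seed = 2026)
message(sprintf("simulating %d years on a %d x %d grid, %d clusters",
                length(cfg$years), cfg$grid$nrow, cfg$grid$ncol,
                cfg$n_clusters))

land <- generate_landscape(cfg)
stack <- build_covariates(land)
truth <- generate_truth_surface(cfg, stack)
clusters <- sample_clusters(truth, stack, cfg)
displaced <- displace_clusters(clusters, displacement_rule(),
                               seed = cfg$seed + 7L)

for (t in cfg$years) {
  yr <- as.character(t)
  write_raster(land$ntl[[yr]],
               file.path(raster_dir, sprintf("ntl_%s.asc", yr)))
  write_raster(land$lulc[[yr]],
               file.path(raster_dir, sprintf("lulc_hr_%s.asc", yr)))
  write_raster(truth$prob[[yr]],
               file.path(raster_dir, sprintf("truth_%s.asc", yr)))
}
write_clusters(clusters, file.path(raster_dir, "clusters_true.csv"))
write_clusters(displaced,
               file.path(raster_dir, "clusters_displaced.csv"))
jsonlite::write_json(
  list(seed = cfg$seed, beta_true = as.list(cfg$beta_true),
       matern_range_true = cfg$matern_range_true,
       matern_sd_true = cfg$matern_sd_true,
       years = cfg$years,
       grid = cfg$grid[c("nrow", "ncol", "xll", "yll", "cellsize")]),
  "results/simulation_manifest.json", auto_unbox = TRUE, digits = NA)

message(sprintf(
  "done: %d clusters (mean %.1f households, %.1f%% electrified), rasters in %s",
  nrow(clusters), mean(clusters$n_households),
  100 * mean(clusters$n_electrified / clusters$n_households),
  raster_dir))
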
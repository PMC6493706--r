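# Shared fixture factory: a small synthetic world with covariates, truth
# surface, clusters and an at-pixel observation table.
tiny_world <- function(dim = 16, years = c(2000, 2013), n_clusters = 200,
                       seed = 1, ...) {
  cfg <- sim_config(grid = grid_spec(dim, dim, 30, -1, 0.045),
                    years = years, n_clusters = n_clusters, seed = seed,
                    ...)
  land <- generate_landscape(cfg)
  stack <- build_covariates(land)
  truth <- generate_truth_surface(cfg, stack)
  clusters <- sample_clusters(truth, stack, cfg)
  obs <- suppressMessages(extract_pixel_covariates(stack, clusters))
  list(cfg = cfg, land = land, stack = stack, truth = truth,
       clusters = clusters, obs = obs)
}

# a flat probability surface for controlled cluster sampling
flat_truth <- function(grid, p, years) {
  prob <- lapply(years, function(t) {
    raster_layer(matrix(p, grid$nrow, grid$ncol), grid,
                 kind = "probability")
  })
  names(prob) <- as.character(years)
  list(prob = prob, field = matrix(0, grid$nrow, grid$ncol))
}
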
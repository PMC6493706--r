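---
title: "Model-based geostatistics for electricity-access mapping: methods and design notes"
author: "elecmbg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based geostatistics for electricity-access mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Household surveys (DHS and related programmes) report, for each sampling
cluster of roughly 24 households, how many have electricity — but only at a
deliberately jittered coordinate, and only where and when a survey took
place. Satellite covariates (nighttime lights, land cover) are observed
everywhere, every year. `elecmbg` implements the model-based-geostatistics
pipeline that bridges the two: it models the cluster-level counts as
binomial draws governed by a latent Gaussian spatial field plus raster-
derived fixed effects, and predicts an annual probability-of-electricity-
access surface on a 5 km grid, together with model selection, held-out
validation, a displacement sensitivity experiment, and population-weighted
trend aggregation. A first-class synthetic-data generator stands in for the
access-restricted survey data and the bulky raster archives, so the entire
pipeline runs — and is tested — end to end from code.

# The model

For cluster $i$ with $n_i$ households, $k_i$ electrified, at location
$x_i$ in year $t_i$:

$$k_i \sim \mathrm{Binomial}(n_i, p_i), \qquad
\mathrm{logit}(p_i) = z_i^\top\beta + S(x_i),$$

with fixed effects $z_i$ (intercept; nighttime-light intensity scaled to
$[0,1]$ by its 6-bit maximum 63; land-cover category dummies with low
biomass as reference; impervious area proportion; proximity to impervious
area; and, in model M3, a year term) and a zero-mean Matern ($\nu = 1$)
Gaussian field $S$ with range $\rho$ and marginal standard deviation
$\sigma_s$. The four candidates are:

* **M1** — fixed effects only (an ordinary logistic-binomial GLM);
* **M2** — M1 plus the spatial field $S(x)$;
* **M3** — M2 plus year as a fixed effect;
* **M4** — fixed effects plus a spatiotemporal field $S_t(x)$, one field
  per year coupled by a first-order autoregression, replacing both the
  static field and the year term.

The link is logistic throughout: it is the standard binomial choice in this
model family and makes M1 an ordinary GLM, which in turn gives the test
suite an exact external oracle (`stats::glm`).

## Covariate engineering

Three covariates are engineered from the land-cover raster:

* the **modal category** at 5 km (ties broken toward the lowest category
  index, a fixed, order-independent rule);
* **IAP**, the fraction of valid high-resolution sub-pixels classified
  impervious within each 5 km pixel;
* **PIA** $= \exp(-d/\sigma_u)$, where $d$ is the planar distance in
  degrees to the nearest impervious pixel centre, truncated to zero beyond
  a 1-degree search radius. The shipped default $\sigma_u = 0.28$ degrees
  is the value estimated from the original continental survey;
  `estimate_sigma_u()` recomputes it for any survey as the population
  standard deviation of the nearest-impervious distances (computed without
  the 1-degree truncation — the truncation is a prediction-time
  convenience, not part of the calibration).

PIA distances are deliberately planar and in degrees, because both the
cutoff radius and $\sigma_u$ are quoted in degrees; buffer and displacement
distances, by contrast, are great-circle kilometres. Covariates at cluster
locations are averaged over a 5 km buffer (the standard remedy for DHS
jitter), over valid pixels only so nodata cannot leak into the design; the
land-cover category uses the buffer mode. The nearest-impervious search
uses pixel centres; PIA is computed at the 5 km grid from the
impervious-bearing mask (IAP > 0), with a switch for the high-resolution
mask, because the source material does not pin down which resolution feeds
the decay.

## Inference: a desk-scale Laplace engine

The latent field is indexed on the prediction grid itself — no triangulated
mesh — which keeps one coordinate system and is exact enough at the grid
sizes this package targets. Its prior precision is the sparse
five-point-stencil Gaussian Markov random field approximating the Matern
($\nu = 1$) operator with Neumann boundaries:
$Q = \tau^2(\kappa^2 M + G)M^{-1}(\kappa^2 M + G)$ with lumped mass
$M = h^2 I$, graph-Laplacian stiffness $G$, $\kappa = \sqrt{8}/\rho$, and
$\tau^2 = 1/(4\pi\kappa^2\sigma_s^2)$ so the implied marginal standard
deviation approximates $\sigma_s$ away from the boundary. On a 40 x 40
grid the implied correlation at distance $\rho$ is about 0.14 against the
closed-form 0.1397, and the interior marginal sd is within about 3% of
nominal; the Neumann boundary inflates variance within roughly one range
of the edge, which is why calibration checks read interior nodes.

Fitting is a nested optimisation. Inside, at fixed $(\rho, \sigma_s)$, a
Newton iteration with step halving maximises the joint posterior of
$(S, \beta)$ ($\beta$ carries a flat prior; a $10^{-8}$ ridge guards the
factorisation). Outside, Nelder-Mead maximises the Laplace-approximated
marginal posterior over $(\log\rho, \log\sigma_s)$ (plus
$\mathrm{atanh}$ of the AR(1) correlation for M4), warm-starting each
inner solve at the previous mode and reusing the symbolic Cholesky
factorisation. Everything is deterministic: fixed starting values
($\rho_0 =$ domain width / 5, $\sigma_{s,0} = 0.5$), no randomness, and
Gauss-Hermite quadrature (32 nodes) wherever a Gaussian expectation is
needed. Posterior standard deviations come from the observed-information
Hessian at the mode, at the optimised hyperparameters (empirical Bayes:
hyperparameter uncertainty is not propagated — a known approximation of
this engine).

Hyperpriors are weakly informative and explicit, since the original
analysis does not state its priors: a penalised-complexity-style range
prior with median at half the domain width, an exponential prior on
$\sigma_s$ with $P(\sigma_s > 1) = 0.1$, and a uniform prior on the AR(1)
correlation. The year fixed effect enters linearly (centred mid-window,
scaled to $[-1,1]$); a per-year-factor option exists behind a flag because
"year as a fixed effect" admits both readings.

Degenerate inputs are contracts, not crashes: an all-zero response
converges to a strongly negative intercept with near-zero predictions; a
rank-deficient design errors naming the offending columns; observations
outside the field grid error with a count.

## Model selection by CPO

Candidates are ranked on the training 70% by the sum of log conditional
predictive ordinates. The training split uses round-half-down sizing,
which reproduces the published 21,080 / 9,035 partition of 30,115
clusters, and is uniform over clusters (the source does not describe
stratification; a stratified option exists behind a flag). The fast CPO
path uses the inverse-posterior-expectation identity
$1/\mathrm{CPO}_i = E[1/f(k_i \mid \eta_i)]$ under the Gaussian marginal
of the linear predictor — deterministic via Gauss-Hermite quadrature. The
exact path refits without observation $i$ and integrates the binomial
mass against the refit's predictive Gaussian; it is the oracle in the
tests (median relative disagreement at $n = 60$ is well under the 10%
working tolerance). Numerically zero CPOs are counted and reported as
failures, never silently dropped; values are clamped to $(0, 1]$ at the
floating-point boundaries.

## Validation with synthetic classes

Cluster proportions $k/n$ are not binary outcomes, so validation draws
Bernoulli($k_i/n_i$) "synthetic class" instances per held-out cluster and
compares them with the thresholded predictions ($p > 0.5$, strictly). The
default is one instance per cluster, matching the published table's
caption; a multi-draw mode averages confusion matrices. Metrics follow the
standard identities (accuracy $= tn + tp$, precision $= tp/(tp+fp)$,
sensitivity $= tp/(tp+fn)$); undefined metrics are `NA` with a warning,
never silently zero.

# The synthetic generator

`sim_config()` defaults encode the study conditions: cluster sizes from a
shifted Poisson $1 + \mathrm{Poisson}(23)$ truncated at 120 (mean 24,
right tail beyond 100 reachable), study years 2000-2013, DHS displacement
caps (urban 2 km; rural 5 km, 1% up to 10 km) with uniform bearing and
uniform-in-distance radii, the far-rural subset chosen by independent
Bernoulli(0.01). Displacement uses the exact spherical destination
formula, so the realised great-circle displacement never exceeds its cap.
The landscape places Gaussian urban-centre kernels on the grid: lights are
the kernel intensity quantised to 0-63 with 2%/year growth; impervious
pixels are Bernoulli draws with probability increasing toward the centres
(drawn once, so built area only grows); the other six land-cover classes
fill the background by quantile cuts of a smooth random field. The truth
surface adds one exactly simulated dense-Cholesky Matern field — a
different route than the GMRF used in fitting, so parameter-recovery tests
cross two independent implementations. Population rasters share the urban
kernels with a lognormal texture and grow geometrically per quinquennium;
annual interpolation is per-pixel geometric, with a linear fallback for
zero-to-positive pixels where geometric growth is undefined.

What the generator does **not** emulate: real African geography and
borders, inter-satellite light calibration artefacts, survey
non-response, within-country displacement restrictions, and the
continental scale (~1.5 M pixels/year). Passing tests therefore certify
the algorithms and their statistical behaviour under the stated
conditions, not performance of the original data products.

# The displacement sensitivity experiment

Per replicate: simulate a landscape, truth surface and ~800 clusters; fit
M3 to the true and to the displaced coordinates (covariates re-extracted
at the displaced locations, as a real analyst must); predict every study
year; and compare the sums of squared errors against the true probability
surface over all pixels. The headline quantity is the mean percent SSE
increment over 20 seeded replicates, reported with its spread because a
single synthetic draw is noisy.

The experiment's grid deserves a note. The SSE increment depends strongly
on observation density: with 800 clusters on a 30 x 30 grid (0.9 clusters
per pixel) the clean fit can reconstruct the realised field almost
exactly, so jitter is very costly (mean increments near 50%); at 40 x 40
the mean is near 24%, at 60 x 60 near 12%. The original survey is far
sparser still (about 21,000 training clusters over ~1.5 M pixels). The
experiment therefore uses the sparsest grid the exact dense-Cholesky truth
simulator comfortably supports, 70 x 70 = 4,900 pixels (~0.16 clusters
per pixel), where the mean increment lands in the high single digits —
the same sign and order as the full-scale figure, with the residual gap
attributable to the density still being an order of magnitude above the
continental one.

# Problem sizes and numerical choices

* Component tests use 10-24 pixel grids and 30-800 clusters; recovery and
  selection studies use 24 x 24 grids at $n = 800$ (50 and 20 replicates);
  the sensitivity experiment uses 70 x 70 at $n = 800$, 20 replicates.
* Inner Newton: gradient tolerance $10^{-8}$, at most 100 iterations,
  error on non-convergence. Outer Nelder-Mead: relative tolerance
  $10^{-6}$ (the demonstration scripts loosen this for the 12,600-node M4
  candidate), at most 200 evaluations.
* Ties: modal land cover to the lowest category index; identical CPO
  scores to the first-listed candidate; classification strictly above the
  threshold, so $p = 0.5$ is "no access".
* Rasters are plain-text ESRI ASCII grids with a JSON sidecar for the
  semantic kind and CRS; values are written at full precision so
  roundtrips are exact. Pixel membership follows the half-open
  north-west-corner convention stated once in `point_to_cell()` and used
  everywhere.
* All random stages take explicit seeds and restore the caller's RNG
  state; derived streams use small fixed offsets from the configured
  seed.

# Known limitations

Empirical-Bayes intervals ignore hyperparameter uncertainty and are
mildly optimistic; the grid-indexed field ties the model resolution to
the prediction resolution; the GMRF boundary inflates variance near the
domain edge; the harmonic-identity CPO is unstable for observations with
large posterior predictive variance (the failure counter makes this
visible); and the engine targets desk-scale grids — the sparse algebra is
the right shape for scaling, but no continental-scale engineering has
been done.
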
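# Frozen designs for the recovery studies.

# Regression-family recovery: one canonical shape per family, evaluated on
# 20 class midpoints, with Gaussian noise at 10% of the curve's range.
# Shapes were designed once for mutual identifiability (strong growth ratio
# for the linear case, pronounced curvature spread for the exponential and
# saturating cases, a wide dynamic range for the semi-log case, a V-shaped
# profile for the piecewise case) and are not revisited.
recovery_designs <- function() {
  x20 <- seq(0.25, 9.75, by = 0.5)
  xlog <- seq(0.05, 9.55, by = 0.5)
  list(
    poly1       = list(x = x20, mu = 0.01 + 0.025 * x20),
    poly2       = list(x = x20, mu = 0.05 + 0.06 * x20 - 0.005 * x20^2),
    exponential = list(x = x20, mu = 0.003 * exp(0.55 * x20)),
    one_phase   = list(x = x20, mu = 0.3 * (1 - exp(-1.0 * x20))),
    semilog     = list(x = xlog, mu = 0.15 + 0.04 * log(xlog)),
    piecewise   = list(x = x20, mu = 0.2 - 0.03 * x20 +
                         0.07 * pmax(x20 - 5, 0), psi = 5)
  )
}

# Runs the study for one family; returns selected family per replicate and
# the piecewise breakpoint estimates.
run_family_recovery <- function(family, n_rep = 200, seed = 1) {
  d <- recovery_designs()[[family]]
  noise <- 0.1 * diff(range(d$mu))
  selected <- character(n_rep)
  psi_hat <- rep(NA_real_, n_rep)
  set.seed(seed)
  for (r in seq_len(n_rep)) {
    y <- d$mu + rnorm(length(d$x), 0, noise)
    fits <- fit_all_families(d$x, y, seed = r)
    selected[r] <- select_model(fits)$family
    if (!is.null(fits$piecewise) && fits$piecewise$converged)
      psi_hat[r] <- fits$piecewise$coefficients[["psi"]]
  }
  list(selected = selected, psi_hat = psi_hat)
}

# Importance-recovery world: isolation planted as the dominant driver with
# effect-size ratio 2 over population and 4 over tourism.
importance_recovery_world <- function(seed) {
  generate_world(world_config(
    seed = seed, regime = "opportunistic",
    lat_range = c(-7, 7), lon_range = c(-9, 9),
    effect_sizes = c(isolation = 1.0, population = -0.5, tourism = 0.25)))
}
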
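# Independent oracles: literal, brute-force implementations kept deliberately
# separate from the package's code paths.

# Modified Shannon evenness, transliterated term by term: shares, raw Shannon
# sum with 0 ln 0 = 0, normalisation by n times the minimum nonzero term.
oracle_evenness <- function(x) {
  total <- 0
  for (xi in x) total <- total + xi
  V <- x / total
  H <- 0
  min_term <- Inf
  n_nonzero <- 0
  for (v in V) {
    if (v > 0) {
      term <- v * log(v)
      H <- H + term
      if (term < min_term) min_term <- term
      n_nonzero <- n_nonzero + 1
    }
  }
  if (n_nonzero == 1) return(0)
  denom <- length(x) * min_term
  if (denom == 0) return(0)
  H / denom
}

# Kendall tau-b by explicit enumeration of all pairs.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tie_x <- tie_y <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- sign(x[j] - x[i]); b <- sign(y[j] - y[i])
    if (a == 0 && b == 0) next
    if (a == 0) tie_x <- tie_x + 1
    else if (b == 0) tie_y <- tie_y + 1
    else if (a == b) conc <- conc + 1
    else disc <- disc + 1
  }
  (conc - disc) / sqrt((conc + disc + tie_x) * (conc + disc + tie_y))
}

# Exhaustive piecewise breakpoint search on a 1e-3-spaced grid inside the
# admissible interval (>= 3 design points on each side).
oracle_piecewise_psi <- function(x, y, step = 1e-3) {
  xs <- sort(unique(x))
  lo <- xs[3] + step
  hi <- xs[length(xs) - 2] - step
  grid <- seq(lo, hi, by = step)
  rss <- vapply(grid, function(psi) {
    X <- cbind(1, x, pmax(x - psi, 0))
    sum(lm.fit(X, y)$residuals^2)
  }, 0)
  list(psi = grid[which.min(rss)], rss = min(rss))
}

# small worlds used across tests
small_world <- function(seed = 1, regime = "mixed", ...,
                        lat_range = c(-5, 5), lon_range = c(-5, 5)) {
  # small mixed worlds can legitimately cap a quota class; irrelevant here
  suppressWarnings(
    generate_world(world_config(seed = seed, regime = regime,
                                lat_range = lat_range,
                                lon_range = lon_range, ...)))
}

filtered <- function(cells) suppressMessages(filter_cells(cells))
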
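#' Regression families for gradient profiles
#'
#' The protected fraction along a gradient is characterised by fitting six
#' candidate shapes to the class-level points (x = class midpoint,
#' y = `FRAC.PROT`) and keeping the AIC-best one:
#'
#' | family        | form                                      | parameters |
#' |---------------|-------------------------------------------|------------|
#' | `poly1`       | `a + b x`                                 | 2          |
#' | `poly2`       | `a + b x + c x^2`                         | 3          |
#' | `exponential` | `a exp(b x)`                              | 2          |
#' | `one_phase`   | `y0 + (plateau - y0) (1 - exp(-k x))`, k>0| 3          |
#' | `semilog`     | `a + b ln x` (requires all x > 0)         | 2          |
#' | `piecewise`   | continuous 2-segment linear, breakpoint ψ | 4          |
#'
#' Nonlinear families use multi-start Levenberg–Marquardt least squares
#' (data-driven start plus seeded random restarts, best residual sum of
#' squares kept). The piecewise breakpoint is found by profiling: for each
#' candidate ψ the model is linear in the remaining coefficients, so ψ is
#' grid-searched over midpoints between interior design points and then
#' refined locally by golden-section search.
#'
#' @name regression_families
NULL

#' Regression family catalogue
#'
#' @return Data frame with columns `family` and `n_params`, in the fixed
#'   selection order (see [regression_families]).
#' @export
family_info <- function() {
  data.frame(
    family = c("poly1", "poly2", "exponential", "one_phase", "semilog",
               "piecewise"),
    n_params = c(2L, 3L, 2L, 3L, 2L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Fit one regression family
#'
#' Least-squares fit of a single family (see [regression_families]) to
#' class-level points. The pseudo-R^2 is the squared Pearson correlation of
#' observed and predicted values.
#'
#' @param x Class midpoints (length >= 8: the modelling floor — re-bin the
#'   histogram first if necessary).
#' @param y Protected fractions per class.
#' @param family One of `"poly1"`, `"poly2"`, `"exponential"`,
#'   `"one_phase"`, `"semilog"`, `"piecewise"`.
#' @param seed Seed for the random multi-starts of nonlinear fits.
#' @param n_starts Number of random restarts on top of the data-driven
#'   start (default 5).
#' @return Object of class `gradient_fit`: list with `family`,
#'   `coefficients`, `n_params`, `rss`, `pseudo_r2`, `predictions`,
#'   `converged`, and `aic` (via [model_aic()]).
#' @examples
#' x <- seq(0.25, 9.75, by = 0.5)
#' fit_family(x, 0.05 + 0.02 * x, "poly1")$coefficients
#' @export
fit_family <- function(x, y, family, seed = 1L, n_starts = 5L) {
  family <- match.arg(family, family_info()$family)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 8L)
    stopf("need >= 8 points to fit a gradient model (got %d): re-bin the histogram",
          length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stopf("x and y must be finite")
  if (family == "semilog" && any(x <= 0))
    stopf("semilog requires all x > 0")

  fit <- switch(family,
    poly1 = fit_lm(x, y, cbind(1, x), c("a", "b")),
    poly2 = fit_lm(x, y, cbind(1, x, x^2), c("a", "b", "c")),
    semilog = fit_lm(x, y, cbind(1, log(x)), c("a", "b")),
    exponential = fit_exponential(x, y, seed, n_starts),
    one_phase = fit_one_phase(x, y, seed, n_starts),
    piecewise = fit_piecewise(x, y)
  )
  if (!fit$converged) {
    return(structure(list(family = family, coefficients = NULL,
                          n_params = family_n_params(family), rss = NA_real_,
                          pseudo_r2 = NA_real_, predictions = NULL,
                          converged = FALSE, aic = NA_real_),
                     class = "gradient_fit"))
  }
  pr2 <- if (sd(fit$predictions) > 0 && sd(y) > 0)
    cor(y, fit$predictions)^2 else 0
  out <- structure(list(family = family, coefficients = fit$coefficients,
                        n_params = family_n_params(family), rss = fit$rss,
                        pseudo_r2 = pr2, predictions = fit$predictions,
                        converged = TRUE, aic = NA_real_),
                   class = "gradient_fit")
  out$aic <- model_aic(out, length(x))
  out
}

family_n_params <- function(family) {
  fi <- family_info()
  fi$n_params[fi$family == family]
}

fit_lm <- function(x, y, X, names) {
  f <- lm.fit(X, y)
  pred <- as.numeric(X %*% f$coefficients)
  list(coefficients = setNames(as.numeric(f$coefficients), names),
       rss = sum((y - pred)^2), predictions = pred, converged = TRUE)
}

# multi-start nonlinear least squares via Levenberg-Marquardt; returns the
# best converged fit or converged = FALSE
multistart_nls <- function(x, y, formula_rhs, starts, lower = NULL) {
  dat <- data.frame(x = x, y = y)
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        stats::as.formula(paste("y ~", formula_rhs)), data = dat,
        start = st, lower = lower %||% rep(-Inf, length(st)),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coefficients = coef(f), rss = rss,
                   predictions = as.numeric(stats::fitted(f)))
  }
  if (is.null(best)) return(list(converged = FALSE))
  c(best, converged = TRUE)
}

fit_exponential <- function(x, y, seed, n_starts) {
  with_seed(seed, {
    starts <- list()
    # data-driven start: log-linear regression on positive y
    pos <- y > 0
    if (sum(pos) >= 2L) {
      ll <- lm.fit(cbind(1, x[pos]), log(y[pos]))$coefficients
      starts[[1]] <- list(a = exp(ll[1]), b = ll[2])
    } else {
      starts[[1]] <- list(a = mean(y), b = 0)
    }
    span <- diff(range(x))
    for (i in seq_len(n_starts))
      starts[[length(starts) + 1L]] <-
        list(a = mean(y) * runif(1, 0.2, 2) * sample(c(-1, 1), 1),
             b = runif(1, -3, 3) / max(span, 1e-9))
    res <- multistart_nls(x, y, "a * exp(b * x)", starts)
    res$coefficients <- if (res$converged)
      setNames(as.numeric(res$coefficients), c("a", "b")) else NULL
    res
  })
}

fit_one_phase <- function(x, y, seed, n_starts) {
  with_seed(seed, {
    y0_hat <- y[which.min(x)]
    pl_hat <- y[which.max(x)]
    span <- diff(range(x))
    starts <- list(list(y0 = y0_hat, plateau = pl_hat,
                        k = 3 / max(span, 1e-9)))
    for (i in seq_len(n_starts))
      starts[[length(starts) + 1L]] <-
        list(y0 = y0_hat + runif(1, -1, 1) * sd(y),
             plateau = pl_hat + runif(1, -1, 1) * sd(y),
             k = exp(runif(1, log(0.1), log(10))) / max(span, 1e-9))
    res <- multistart_nls(x, y, "y0 + (plateau - y0) * (1 - exp(-k * x))",
                          starts, lower = c(-Inf, -Inf, 1e-8))
    res$coefficients <- if (res$converged)
      setNames(as.numeric(res$coefficients), c("y0", "plateau", "k")) else NULL
    res
  })
}

# profiled piecewise fit: for fixed psi the model a + b x + c (x - psi)_+ is
# linear; grid over midpoints between interior sorted x then golden-section
# refinement around the grid winner
piecewise_rss <- function(psi, x, y) {
  X <- cbind(1, x, pmax(x - psi, 0))
  r <- lm.fit(X, y)$residuals
  sum(r^2)
}

fit_piecewise <- function(x, y) {
  xs <- sort(unique(x))
  if (length(xs) < 4L) return(list(converged = FALSE))
  mids <- (xs[-1] + xs[-length(xs)]) / 2
  # identifiability guard: keep >= 3 design points strictly on each side so
  # both segments retain residual degrees of freedom (an edge-parked
  # breakpoint fits its outer segment exactly and is pure overfitting)
  cand <- mids[vapply(mids, function(m)
    sum(xs < m) >= 3L && sum(xs > m) >= 3L, TRUE)]
  if (!length(cand))
    cand <- mids[vapply(mids, function(m)
      sum(xs < m) >= 2L && sum(xs > m) >= 2L, TRUE)]
  if (!length(cand)) return(list(converged = FALSE))
  rss_grid <- vapply(cand, piecewise_rss, 0, x = x, y = y)
  i <- which.min(rss_grid)
  lo <- if (i > 1L) cand[i - 1L] else cand[i]
  hi <- if (i < length(cand)) cand[i + 1L] else cand[i]
  psi <- if (hi > lo)
    optimize(piecewise_rss, c(lo, hi), x = x, y = y, tol = 1e-8)$minimum
  else cand[i]
  if (piecewise_rss(cand[i], x, y) < piecewise_rss(psi, x, y))
    psi <- cand[i]
  X <- cbind(1, x, pmax(x - psi, 0))
  f <- lm.fit(X, y)
  pred <- as.numeric(X %*% f$coefficients)
  list(coefficients = setNames(c(as.numeric(f$coefficients), psi),
                               c("a", "b", "c", "psi")),
       rss = sum((y - pred)^2), predictions = pred, converged = TRUE)
}

#' Gaussian AIC of a gradient fit
#'
#' `AIC = n ln(rss / n) + 2 (k + 1)` with `k` the number of model
#' parameters; the `+ 1` counts the error variance. The same formula is
#' applied to every family, which makes AIC differences comparable across
#' them. A perfect fit (`rss = 0`) returns `-Inf` as a sentinel.
#'
#' @param fit A `gradient_fit`.
#' @param n_points Number of fitted points; must exceed `k + 2`.
#' @return AIC value.
#' @examples
#' # n = 10, rss = 1, k = 2:  10 * log(0.1) + 6
#' @export
model_aic <- function(fit, n_points) {
  stopifnot(inherits(fit, "gradient_fit"))
  k <- fit$n_params
  if (n_points <= k + 2)
    stopf("AIC needs n > k + 2 (n = %d, k = %d)", n_points, k)
  if (!is.finite(fit$rss)) return(NA_real_)
  if (fit$rss <= 0) return(-Inf)
  n_points * log(fit$rss / n_points) + 2 * (k + 1)
}

#' Fit all applicable families
#'
#' Fits every requested family to the same points; `semilog` is skipped when
#' any x is nonpositive, and families whose optimiser fails to converge are
#' marked failed and excluded from selection.
#'
#' @inheritParams fit_family
#' @param families Families to try (default all six).
#' @return Named list of `gradient_fit` objects.
#' @export
fit_all_families <- function(x, y, families = family_info()$family,
                             seed = 1L, n_starts = 5L) {
  families <- match.arg(families, family_info()$family, several.ok = TRUE)
  fits <- list()
  for (fam in families) {
    if (fam == "semilog" && any(x <= 0)) next
    fits[[fam]] <- tryCatch(
      fit_family(x, y, fam, seed = seed, n_starts = n_starts),
      error = function(e) NULL)
  }
  Filter(Negate(is.null), fits)
}

#' Select the AIC-best family
#'
#' Minimum-AIC selection over converged fits. Ties (AIC difference below
#' `1e-6`) are broken by fewer parameters, then by the fixed family order
#' `poly1, poly2, exponential, one_phase, semilog, piecewise`.
#'
#' @param fits List of `gradient_fit` objects (from [fit_all_families()]).
#' @return The selected `gradient_fit`.
#' @export
select_model <- function(fits) {
  fits <- Filter(function(f) isTRUE(f$converged) && is.finite(f$rss), fits)
  if (!length(fits)) stopf("all regression families failed")
  aics <- vapply(fits, function(f) f$aic, 0)
  cand <- which(aics - min(aics) < 1e-6)
  if (length(cand) > 1L) {
    np <- vapply(fits[cand], function(f) f$n_params, 0L)
    cand <- cand[np == min(np)]
    if (length(cand) > 1L) {
      ord <- match(vapply(fits[cand], function(f) f$family, ""),
                   family_info()$family)
      cand <- cand[which.min(ord)]
    }
  }
  fits[[cand[1]]]
}

#' @export
print.gradient_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("gradient_fit [%s]: failed to converge\n", x$family))
    return(invisible(x))
  }
  cat(sprintf("gradient_fit [%s]: rss = %.4g, AIC = %.3f, pseudo-R2 = %.3f\n",
              x$family, x$rss, x$aic, x$pseudo_r2))
  cat("  coefficients:",
      paste(sprintf("%s = %.4g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  invisible(x)
}

#' Class midpoints of a histogram
#'
#' The abscissa used for class-level regression. Interior classes use the
#' arithmetic midpoint of their bounds; the pooled tail classes use the
#' midpoint of their (possibly extended) reported bounds.
#'
#' @param histogram A `gradient_histogram`.
#' @param nonempty_only Drop empty classes (default TRUE, matching the
#'   statistics).
#' @return Numeric vector of midpoints.
#' @export
class_midpoints <- function(histogram, nonempty_only = TRUE) {
  cls <- histogram$classes
  if (nonempty_only) cls <- cls[cls$area_km2 > 0, , drop = FALSE]
  (cls$lower + cls$upper) / 2
}

#' Fit the family suite to a histogram's protected-fraction profile
#'
#' @param histogram A `gradient_histogram` with >= 8 nonempty classes.
#' @param measure `"frac_prot"` (default) or `"area_prot_km2"`.
#' @inheritParams fit_all_families
#' @return List with `fits` (all families) and `selected`.
#' @export
regress_histogram <- function(histogram, measure = c("frac_prot",
                                                     "area_prot_km2"),
                              families = family_info()$family, seed = 1L) {
  measure <- match.arg(measure)
  cls <- histogram$classes[histogram$classes$area_km2 > 0, , drop = FALSE]
  x <- (cls$lower + cls$upper) / 2
  y <- cls[[measure]]
  fits <- fit_all_families(x, y, families = families, seed = seed)
  list(variable = histogram$variable, region = histogram$region,
       measure = measure, fits = fits, selected = select_model(fits))
}
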
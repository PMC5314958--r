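#' Normalise a gradient measure into shares
#'
#' Divides a nonnegative measure vector (per-class protected fractions or
#' protected areas) by its sum, turning it into probabilities
#' `V_j = x_j / sum(x)`.
#'
#' @param x Nonnegative numeric vector, length >= 2, positive sum.
#' @return Shares summing to 1.
#' @examples
#' normalize_shares(c(2, 2, 4))
#' @export
normalize_shares <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    stopf("x must be a numeric vector of length >= 2")
  if (any(!is.finite(x))) stopf("x must be finite")
  if (any(x < 0)) stopf("x must be nonnegative")
  s <- sum(x)
  if (s <= 0) stopf("no protection along gradient: sum(x) = 0")
  x / s
}

#' Modified Shannon evenness of a gradient profile
#'
#' Quantifies how evenly a measure `x` is spread along an ordered gradient.
#' With shares `V_j = x_j / sum(x)`, the raw Shannon sum is
#' `H = sum_j V_j * ln(V_j)` (taking `0 * ln 0 = 0`), and the index is
#'
#'   `H' = H / (n * min_j V_j * ln(V_j))`,
#'
#' where `n` is the number of classes and the minimum runs over classes with
#' a nonzero share. Because every term of `H` is bounded by the minimum
#' term, `H'` lies in `[0, 1]` and equals exactly 1 whenever `x` is constant
#' along the gradient — more generally whenever all nonzero `V ln V` terms
#' coincide. When a single class holds all the mass both numerator and
#' denominator vanish; by continuity with a vanishing second class the index
#' is defined as 0 (total concentration).
#'
#' Zero-share classes contribute nothing to `H` and are excluded from the
#' minimum (they would otherwise force the denominator to 0 and degenerate
#' the index); they still count in `n`.
#'
#' Applied to `FRAC.PROT` the index measures *fraction* representativeness
#' (is the same share of every environment protected?); applied to
#' `AREA.PROT` it measures *quota* representativeness (does every
#' environment hold the same absolute protected area?).
#'
#' @param x Nonnegative measure vector over the (nonempty) gradient
#'   classes, length >= 2.
#' @param measure Optional label stored in the result.
#' @return Object of class `evenness_result`: list with `measure`, `x`, `V`
#'   (shares), `H`, `H_prime`, and `n`.
#' @examples
#' evenness(rep(0.37, 5))$H_prime        # exactly 1
#' evenness(c(0.7, 0.2, 0.1))$H_prime    # ~0.83
#' @export
evenness <- function(x, measure = NA_character_) {
  V <- normalize_shares(x)
  n <- length(V)
  terms <- ifelse(V > 0, V * log(V), 0)
  H <- sum(terms)
  nz <- V > 0
  H_prime <- if (sum(nz) == 1L) 0 else {
    denom <- n * min(terms[nz])
    if (denom == 0) 0 else H / denom
  }
  structure(list(measure = measure, x = x, V = V, H = H,
                 H_prime = H_prime, n = n),
            class = "evenness_result")
}

#' @export
print.evenness_result <- function(x, ...) {
  cat(sprintf("evenness_result%s: n = %d, H = %.5f, H' = %.5f\n",
              if (is.na(x$measure)) "" else paste0(" [", x$measure, "]"),
              x$n, x$H, x$H_prime))
  invisible(x)
}

#' Fraction vs quota representativeness of one histogram
#'
#' Computes the modified Shannon evenness of `FRAC.PROT` (fraction
#' representativeness) and of `AREA.PROT` (quota representativeness) over
#' the nonempty classes of a gradient histogram, and their ratio. A ratio
#' above 1 means protection follows fraction representativeness more
#' closely than quota representativeness along this gradient.
#'
#' @param histogram A [build_histogram()] result with at least two nonempty
#'   classes.
#' @return List with `variable`, `region`, `n_classes`, `H_fraction`,
#'   `H_quota` (both `evenness_result`s), and `ratio`
#'   (`H'_fraction / H'_quota`; `NA` when `H'_quota` is 0).
#' @export
compare_representativeness <- function(histogram) {
  stopifnot(inherits(histogram, "gradient_histogram"))
  cls <- histogram$classes[histogram$classes$area_km2 > 0, , drop = FALSE]
  if (nrow(cls) < 2L)
    stopf("histogram %s x %s has fewer than 2 nonempty classes",
          histogram$variable, histogram$region)
  ev_frac <- evenness(cls$frac_prot, measure = "FRAC_PROT")
  ev_quota <- evenness(cls$area_prot_km2, measure = "AREA_PROT")
  list(variable = histogram$variable, region = histogram$region,
       n_classes = nrow(cls),
       H_fraction = ev_frac, H_quota = ev_quota,
       ratio = if (ev_quota$H_prime > 0)
         ev_frac$H_prime / ev_quota$H_prime else NA_real_)
}
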
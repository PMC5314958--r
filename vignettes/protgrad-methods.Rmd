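---
title: "Gradient analysis of protected-area representativeness: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gradient analysis of protected-area representativeness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the data model

Where, along the world's biophysical, human, and biological gradients, has
land protection actually been placed? `protgrad` answers this for gridded
data: the unit of observation is a half-degree grid cell carrying its
spherical-band area, the fraction of that area that is land, the fraction of
the land that is under strict protection, a region label, and fifteen
covariates in three groups — six *biophysical* variables (temperature,
precipitation, water balance, elevation, slope, soil fertility) whose even
coverage defines representativeness, five *preferential* variables (tourism
attractiveness, distance to international frontiers, standing biomass, and
animal and vascular-plant richness), and four *opportunistic* variables
(population, isolation from cities, distance to coasts, cropland
suitability). Cells with less than 5% land are excluded before any
statistic is computed.

Three summaries are carried per class $j$ of a gradient histogram: the
terrestrial area `AREA`, the protected area `AREA.PROT`, and the protected
fraction `FRAC.PROT` $=$ `AREA.PROT`$/$`AREA`, i.e. the area-weighted mean
of cell-level protected fractions. This last identity is chosen
deliberately: it is the unique reading that conserves totals exactly under
any re-binning, and conservation is the invariant the test suite leans on.

## Histogram construction

Class widths are set once, on the global distribution of each variable, as
one twentieth of its central 95% span (the 2.5–97.5 percentile range,
unweighted), and the same width and boundaries are reused for every region
so regional histograms remain comparable. Cells outside the percentile
range are pooled into the first or last class — pooling changes class
membership, never totals. Intervals are half-open $[l, u)$ with the last
class closed. Empty interior classes are kept in the structure with zero
area but are excluded from all statistics. If a histogram has fewer than 8
nonempty classes the width is halved and the histogram rebuilt until the
rule is met (giving up below $2^{-10}$ of the initial width); all
class-level statistics require at least 8 classes.

## The modified Shannon evenness index

For a measure $x_j \ge 0$ over $n$ classes, with shares
$V_j = x_j / \sum_k x_k$:

$$H = \sum_j V_j \ln V_j, \qquad
  H' = \frac{H}{n \cdot \min_j\,(V_j \ln V_j)},$$

where the minimum runs over classes with $V_j > 0$ and $0 \ln 0 := 0$.
Every term of $H$ is bounded in magnitude by the minimum term, so
$H' \in [0, 1]$, and $H' = 1$ exactly when the measure is constant along
the gradient. Applied to `FRAC.PROT` the index diagnoses **fraction
representativeness** (a constant share of every environment protected);
applied to `AREA.PROT` it diagnoses **quota representativeness** (a
constant absolute area per environment).

Numerical conventions, each forced by a degenerate case:

* zero-share classes are excluded from the min term — otherwise any empty
  class would zero the denominator and the index would be undefined for
  most real histograms; they still count in $n$;
* if a single class holds all the mass, numerator and denominator both
  vanish; the limit of a vanishing second class gives 0, so $H' := 0$
  (total concentration);
* the index has a documented quirk: it equals 1 whenever all nonzero
  $V \ln V$ terms coincide, which can happen for unequal shares (e.g.
  $(0.5, 0.25, 0.25)$, since $0.5\ln 0.5 = 0.25\ln 0.25$). A regression
  test pins this behaviour so it is never "fixed" silently.

The index is scale-invariant, permutation-invariant, and is checked against
a brute-force transliteration of the formulas on a thousand random vectors
to $10^{-12}$.

## Regression families along gradients

The shape of `FRAC.PROT` against class midpoints (preferential and
opportunistic variables) is characterised by six least-squares families:
linear and quadratic polynomials, the exponential $a e^{bx}$, the one-phase
association $y_0 + (\text{plateau} - y_0)(1 - e^{-kx})$ with $k > 0$, the
semi-log $a + b \ln x$ (only when all $x > 0$), and a continuous two-segment
linear model with breakpoint $\psi$. Selection is by Gaussian AIC,
$n \ln(\mathrm{rss}/n) + 2(k+1)$, identical across families ($k$ = 2, 3, 2,
3, 2, 4 parameters respectively; the $+1$ counts the error variance); ties
below $10^{-6}$ go to the fewer-parameter family, then to the fixed family
order. AIC rather than AICc is used — the criterion the procedure names —
with roughly 20 classes the difference is small; goodness of fit is
reported as the squared observed–predicted correlation (pseudo-$R^2$).

Nonlinear families are fitted by Levenberg–Marquardt with a data-driven
start plus five seeded random restarts, keeping the best residual sum of
squares; a family that never converges is dropped from selection rather
than failing the analysis. The breakpoint is profiled: for fixed $\psi$ the
piecewise model is linear, so $\psi$ is grid-searched over midpoints
between adjacent design points and then refined by golden-section search.
The breakpoint is constrained to keep at least three design points strictly
on each side, the standard segmented-regression stability bound: an
edge-parked breakpoint lets the outer segment interpolate two points with
zero residual degrees of freedom, which is overfitting rather than a model.

The package's model-recovery study (simulate from each family at Gaussian
noise with sd equal to 10% of the curve's range over 20 classes, re-select
by AIC, 200 replicates) uses one canonical shape per family, designed once
for mutual identifiability: a steep linear trend (so exponential curvature
cannot mimic it), a quadratic hump, a strongly convex exponential, a sharp
one-phase saturation, a semi-log profile over a two-decade abscissa, and a
V-shaped piecewise profile. The known hard confusions are piecewise versus
poly2, and — for any *linear* truth — the nested quadratic and piecewise
families, which plain AIC spuriously prefers in roughly a quarter of
replicates combined at $n = 20$; this is a property of AIC selection
itself, is independent of the linear shape chosen (any linear truth is
affinely equivalent), and is reported by the study rather than hidden.

## Random-forest importance

The relative influence of preferential versus opportunistic variables on
the per-cell protected fraction is ranked by permutation importance from a
regression random forest (500 fully grown trees, terminal node size 1):
the increase in out-of-bag MSE when a predictor's out-of-bag values are
permuted, averaged over trees and normalised by its standard deviation.
`mtry` is tuned by refitting the forest at every value $1..p$ from a fixed
seed and keeping the OOB-MSE minimiser (ties to the smaller value).
Biophysical variables are excluded from the forest: their importance would
measure representativeness itself, not a preference or opportunity.

For reporting, negative raw importances are clipped to zero and the rest
rescaled to percentages summing to 100 (raw values are kept for audit).
Group averages pre-average animal and plant richness into a single
biological-conservation value before averaging the preferential group —
the two richness variables depict one motivation, and without
pre-averaging it would be counted twice.

The forest runs on cells, not on histogram classes: a multivariate model
needs joint covariate observations, which single-variable class summaries
cannot supply. Class-level analyses (evenness, regression) and cell-level
analyses (forest, Kendall correlations) therefore coexist in one pipeline.

## The synthetic world

Because the real inputs are large external rasters, the package carries a
generator that emulates their statistical structure on a configurable
grid. Cell areas use the spherical band formula with $R = 6371$ km (no
ellipsoid; the error is below 0.5% and cancels from all ratios). Land is a
smooth random field thresholded so a configurable share of cells
(default 0.7) is predominantly terrestrial. Covariates are built from a
joint latent Gaussian field — half white noise, half smooth plane-wave
fields with patches on the order of 8° — multiplied by the Cholesky factor
of a requested correlation matrix (rejected if not positive-definite), then
pushed through monotone marginal transforms: log-normal for the skewed
human and biological variables (population most heavily), a bounded
logistic for cropland suitability, a latitudinal gradient on the climate
latents. Monotone transforms preserve rank statistics, so a requested
latent correlation $\rho$ yields a Kendall $\tau = \frac{2}{\pi}
\arcsin \rho$ in expectation; the default correlations are set so the
realised $\tau$ between richness and cropland suitability is 0.26
(animals) and 0.40 (plants), the magnitudes reported for real global data,
with population–isolation negatively coupled.

Protection regimes realise the four canonical spatial patterns:

* **fraction** — every cell's protected fraction is the target rate plus
  logit-scale noise, independent of all covariates, so every class of any
  gradient is protected at the same rate;
* **quota** — the driver gradient is split into the same 20
  percentile-truncated classes the analysis uses and each class receives
  an equal absolute protected area, spread within the class in proportion
  to terrestrial area (an infeasible quota is capped at the class area
  with a warning);
* **preferential / opportunistic** — the protected fraction is a logistic
  function of the named drivers' normal scores with signed effect sizes
  plus Gaussian noise (default sd 0.25 on the logit scale), the intercept
  calibrated so the area-weighted mean equals the target share
  (default 0.154, the global strictly-protected share);
* **mixed** — a convex combination, used to plant a known dominance order
  of drivers.

The default extent (25° × 50° at 0.5° resolution, 5 000 grid cells, seven
longitudinal region bands) is the scale at which all distributional checks
are run; the importance-recovery study uses a 14° × 18° world
(roughly 900 analysed cells) so that twenty replicates of a fully tuned
500-tree forest remain a short desk-scale computation. What the generator
does *not* emulate: polygon geometry of individual protected areas (only
per-cell fractions, which is all the statistics consume), spatial
autocorrelation of the residual noise, temporal dynamics of protection,
and real coastline/region shapes. Passing recovery tests therefore show
that the estimators recover planted structure of realistic strength and
correlation — not that real-world estimates are unbiased under
spatial dependence.

## Reproducibility and degenerate inputs

Every stochastic step (world generation, forest bootstraps, multi-start
restarts) derives from an explicit integer seed and restores the session
RNG afterwards; rerunning a pipeline configuration reproduces every output
file byte for byte. Degenerate inputs fail loudly and specifically:
constant variables cannot define class widths, gradients with no
protection cannot be normalised into shares, histograms with fewer than
two nonempty classes have no evenness, fewer than eight points refuse a
regression, fewer than fifty cells refuse OOB tuning, and a cell table
with an out-of-range value is rejected naming the row and column.

## Known limitations

* The evenness index's equal-term quirk (above) means $H' = 1$ is
  necessary but not sufficient for a constant profile.
* AIC selection at ~20 classes over-selects the 4-parameter piecewise
  family at a rate of roughly 15–30% when the truth is one of its nested
  special cases; conclusions about *which* nonlinear shape fits best
  should lean on the pseudo-$R^2$ and on inspection, not on the family
  label alone.
* Permutation importance inherits the known collinearity behaviour of
  random forests: correlated predictors share importance. The planted
  dominance order is recovered reliably at effect ratios of 2 and above;
  closer ratios are not resolved.
* Class-level regression treats pooled tail classes like interior ones at
  their midpoint; with heavy tails the first/last midpoints are coarse
  summaries.
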
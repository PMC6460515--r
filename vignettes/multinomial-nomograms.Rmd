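---
title: "Methods: parallel-scale nomograms and scoring charts for multinomial models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parallel-scale nomograms and scoring charts for multinomial models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multinomogram)
```

## The model and its additive decomposition

The package works with an already-fitted multinomial logistic regression
model: `K` mutually exclusive outcome categories, the `K`-th acting as
reference, and `J` covariates. For covariate vector $x$,

$$\mathrm{lp}_k(x) = \alpha_k + \beta_k' x, \qquad
\pi_k(x) = \frac{e^{\mathrm{lp}_k(x)}}{1 + \sum_p e^{\mathrm{lp}_p(x)}},
\qquad
\pi_K(x) = \frac{1}{1 + \sum_p e^{\mathrm{lp}_p(x)}}.$$

Taking logarithms splits every category's log probability into a
category-specific part and a shared part:

$$\ln \pi_k = \underbrace{\mathrm{lp}_k}_{l} +
\underbrace{\left(-\ln\!\big[1 + \textstyle\sum_p
e^{\mathrm{lp}_p}\big]\right)}_{s},$$

with $\ln \pi_K = s$ for the reference. An additive relation $o = l + s$
is exactly what a parallel-scale nomogram can solve graphically, and the
whole construction rests on this identity. The model is assumed to
contain first-order main effects only: the points system assigns one
independent row per (covariate, category) pair, which has no faithful
graphical analogue for interaction or spline terms.

Covariates are `continuous` (with a declared relevant range) or `binary`
(0/1); multi-level factors must arrive pre-coded as dummies. The
declared ranges are part of the model specification: they determine the
points standardization and the default axis ranges, and profile values
outside them raise an error by default. An opt-in `clamp` mode truncates
to the range instead, for batch scoring of data that may contain mild
excursions; clamping changes predictions for such rows and is therefore
never silent default behaviour.

## Nomogram geometry

The `L` (linear predictor) and `S` (shared term) axes share a height `h`
and sit a distance `d` apart; both are in arbitrary length units (the
renderer maps one unit to a configurable number of pixels, 40 by
default). Given value ranges $[l^{low}, l^{up}]$ and $[s^{low},
s^{up}]$,

$$m_1 = \frac{h}{l^{up}-l^{low}}, \quad
m_3 = \frac{h}{s^{up}-s^{low}}, \quad
m_2 = \frac{m_1 m_3}{m_1 + m_3}, \quad
d_{LO} = d - \frac{d}{m_1/m_3 + 1} = \frac{d\,m_1}{m_1+m_3}.$$

The constructor computes $d_{LO}$ both ways and refuses to continue if
they disagree beyond $10^{-12} d$ — a cheap guard against regressions in
the scaling algebra. All three axes share a common baseline: position 0
on each axis corresponds to that axis's lower value. This convention is
what makes the isopleth identity exact: the straight line through
$(0,\, m_1(l - l^{low}))$ and $(d,\, m_3(s - s^{low}))$ crosses the
vertical at $d_{LO}$ at height $m_2(l + s - o^{low})$, algebraically
exactly, where $o^{low} = l^{low} + s^{low}$.

The middle `O` axis is a log-transformed probability scale: a
probability $p$ sits at $m_2(\ln p - o^{low})$. We define $o^{low}$ on
the log scale (the sum of the axis minima) and label the axis with
arithmetic probabilities between $e^{o^{low}}$ and 1; the tick-position
map is applied to $\ln p$ directly, with no further transformation. Two
presentational choices in the source construction are resolved here in
the only way that keeps the collinearity identity exact: the `S` tick
position uses the `S` axis's own lower bound, $m_3(s_t - s^{low})$
(the symmetric analogue of the `L` formula; any other anchor pushes
ticks off the axis), and the `O` scale is handled entirely on the log
scale as above.

The `S` axis is *positioned* on $s$ but *labeled* by
$g = \sum_p e^{\mathrm{lp}_p}$, the quantity a scoring chart delivers;
$s = -\ln(1+g)$ is monotone decreasing, so larger labels sit lower on
the axis. This orientation is fixed by the sign of $s$ and documented
rather than configurable.

### Default axis ranges

When the user does not supply ranges, they are derived from the
covariate box (the product of the declared covariate ranges). Each
linear predictor is affine, so its extremes over the box are attained at
the $2^J$ vertices, and `l_range` is exact vertex enumeration. The sum
$g(x)$ is a sum of exponentials of affine functions and hence convex:
its maximum (which gives $s^{low}$) is also attained at a vertex, but
its minimum (which gives $s^{up}$) can lie in the interior. We therefore
polish the best vertex with box-constrained `L-BFGS-B` minimization of
$g$ (binary covariates relaxed to $[0,1]$, which can only widen the
range, the safe direction). This guarantees every in-range profile maps
into the axis ranges — vertex enumeration alone does not, and the
verification suite samples profiles everywhere in the box. Beyond
`vertex_cap = 20` covariates the enumeration would be slow, and
conservative coordinate-wise bounds (each linear predictor maximized
independently) are used instead, with a warning; these always contain
the exact ranges. Ranges can also be taken from a supplied data frame of
profiles, mirroring the practice of ranging axes by the development
data; the development data for the packaged example are not distributed,
which is why the covariate box is the default.

Degenerate models (every linear predictor constant over the box) have no
usable axis range and raise an error asking for explicit ranges.

## The scoring chart

The rescaling factor anchors the largest conditional covariate effect at
100 points:

$$r = \frac{100}{\max_{j,k} |\beta_{jk}(x^{up}_j - x^{low}_j)|},
\qquad \beta^*_{jk} = r\,\beta_{jk},$$

$$\mathrm{Points}_{jk}(x) = \beta^*_{jk} x -
\min(\beta^*_{jk} x^{up}_j,\ \beta^*_{jk} x^{low}_j),$$

so every points map is non-negative over its covariate range regardless
of the coefficient's sign, spans $[0, 100]$, and the maximum span is
exactly 100 by construction. Baselines absorb the intercepts and the
standardization shifts:

$$bl_k = r\alpha_k + \sum_j \min(\beta^*_{jk} x^{up}_j,\
\beta^*_{jk} x^{low}_j), \qquad bl^*_k = bl_k - \min_k bl_k,$$

so the smallest standardized baseline is zero (ties in the minimum need
no breaking — the subtraction is well defined either way, as in the
bundled example where two categories tie). Total points
$\mathrm{Total}_k = bl^*_k + \sum_j \mathrm{Points}_{jk}(x_j)$ encode
the linear predictor affinely, $\mathrm{lp}_k = (\mathrm{Total}_k +
\min_k bl_k)/r$, which is also how the nomogram's `L` axis is relabeled
in total-points units. The exponentiation axis applies
$\exp\{(\mathrm{Total} + \min_k bl_k)/r\}$ and the sum of its values
over the non-reference categories is exactly the `S`-axis label $g$.

All internal computation keeps full double precision. Rounding points to
integers — how a printed chart is used by hand — happens only on request
(`integer_points`), at reading/rendering time. With `J` covariate
roundings and one baseline rounding of at most half a point each, the
linear predictor moves by at most $(J+1)\,0.5/r$, and the induced
absolute probability error is bounded by $e^{(J+1)0.5/r} - 1$; the test
suite asserts this bound empirically on random models. A covariate with
a zero coefficient for some category keeps its (zero-width) chart row as
an explicit "0 points" annotation, so every category has a structurally
identical row set.

## Numerical choices

- $s$ and the probabilities are evaluated with log-sum-exp
  stabilization, so user-supplied models with extreme coefficients do
  not overflow; the construction itself assumes exact arithmetic.
- The reference category defaults to the *last* listed, and can be
  flagged explicitly in the JSON specification; an explicit flag avoids
  silent misordering when category lists are edited.
- Axis range checks use a relative tolerance of $10^{-7}$ of the axis
  width (and $10^{-9}$ for covariate ranges): the position formulas are
  affine and extrapolate exactly, so the tolerance only affects when an
  error is raised, never the value computed. `clamp = TRUE` truncates
  instead of erroring throughout.
- Tick sequences use base R's 1-2-5 "nice number" steps (`pretty()`) on
  linear axes and explicit 1-2-5-per-decade sequences on the log axes,
  thinned to powers of ten, and then to a minimum spacing of $0.032h$,
  whenever a log axis spans many decades — label legibility is an
  implementation choice the construction leaves open.
- SVG is the single canonical output: text, diffable, and byte-stable
  (fixed number formatting, fonts referenced by generic family only).
  Every tick carries `data-value`/`data-pos` attributes so tests can
  re-derive the drawing from the geometry operations. A fingerprint of
  the model's numeric content is stored in both layout and chart, and
  rendering refuses to mix objects built from different models.

## The random-model generator

`random_model()` draws test models, not clinical ones: intercepts from
$N(0,1)$, coefficients from $N(0,0.8)$, each covariate binary with
probability 0.4 and otherwise continuous with a uniform lower bound in
$[-3, 1]$ and width in $[0.5, 4]$. These scales give linear predictors
mostly within a few log-odds units of zero — the regime of realistic
risk models — while still exercising sign changes, near-zero effects and
categories of widely different baseline risk. What the generator
emulates is the *algebraic shape* of a fitted model; it does not emulate
correlated covariates, rare categories, separation, or the sampling
noise of an actual fit, so passing property suites demonstrates the
correctness of the construction, not the clinical performance of any
model. Profile sampling is uniform over the covariate box (fair coins
for binaries), which deliberately stresses the axis-range logic at the
box edges.

The verification suite (`check_model()` and the test suite) asserts, per
profile: probabilities sum to 1 within $10^{-12}$; the geometric
isopleth reading matches each non-reference probability within $10^{-9}$
relative; the full scoring-chart route (points, totals, exponentiation
axis, $S$ label, nomogram read) matches within $10^{-9}$; and all points
lie in $[0, 100]$. The shipped tests run these on 1000 seeded models
with one random profile each (plus 100 binary-reduction models at
$10^{-12}$); observed worst-case deviations are at machine precision,
orders of magnitude below the asserted tolerances. These problem sizes
keep the full suite in the tens of seconds on a single core while
covering model shapes from $K=2, J=1$ up to $K=5, J=5$.

## The packaged example model

The bundled antepartum operative-delivery model is supplied as published
coefficients (four non-reference categories, seven covariates). Two
caveats are recorded in the fixture's metadata and matter for
interpretation:

- The published coefficient table is rounded. Evaluating the published
  hypothetical case through the rounded coefficients gives probabilities
  (0.108, 0.078, 0.082, 0.253, 0.479), close to but not identical with
  the originally printed values, which came from the unrounded
  development model. The package asserts its own values exactly and the
  printed values only within a 0.05 envelope. Similarly, a handful of
  the printed odds ratios were evidently computed from unrounded
  coefficients and do not round-trip from the printed ones; tests check
  only the consistent cells.
- The development-data covariate ranges were not published. The fixture
  ships plausible clinical ranges (age 16–45 years, gestational age
  36–43 weeks, estimated birth weight 2000–5000 g), flagged
  `synthetic_ranges` in its metadata. Points and totals depend on the
  ranges, so the package's total points differ from the originally
  printed ones by design; probabilities are range-independent.

## Known limitations

- Interaction and higher-order terms are out of scope; pre-compute them
  only if you also accept that each derived column gets its own chart
  row with its own declared range.
- Confidence intervals and model-validation statistics (calibration,
  discrimination) are not computed: the package reports a model, it does
  not assess one.
- The conservative fallback ranges above `vertex_cap` covariates can be
  much wider than achievable, compressing the usable part of the axes.
- SVG output is deliberately plain; publication typography is left to
  downstream vector editors.
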
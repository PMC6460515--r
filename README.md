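# multinomogram

Parallel-scale nomograms and standardized scoring charts for multinomial
logistic prediction models with any number of outcome categories.

## The problem

Clinical prediction often has to distinguish between more than two
outcomes — a differential diagnosis, or competing delivery outcomes for a
laboring woman. Multinomial logistic regression handles this naturally,
but turning a fitted coefficient table into predicted probabilities for
an individual patient takes a chain of careful calculations, which is why
such models are rarely reported graphically. For *K* outcome categories
(category *K* the reference) and covariate vector *x*, the model is

```
lp_k(x) = α_k + β'_k x                       k = 1, …, K−1
π_k(x)  = exp{lp_k(x)} / (1 + Σ_p exp{lp_p(x)})
π_K(x)  = 1 / (1 + Σ_p exp{lp_p(x)})
```

On the log scale every category probability decomposes additively,

```
ln π_k = lp_k + s,      s = −ln(1 + Σ_p exp{lp_p(x)}),
```

with one term specific to the category (*lp_k*) and one term shared by
all categories (*s*). Any relation of the form *result = f + g* can be
solved graphically with a **parallel-scale nomogram**: three parallel
vertical axes *L* (linear predictor), *O* (probability, log scale) and
*S* (shared term, labeled by Σ exp(lp)), scaled by factors
*m₁ = h/(l^up − l^low)*, *m₃ = h/(s^up − s^low)* and
*m₂ = m₁m₃/(m₁+m₃)*, with the middle axis at horizontal offset
*d_LO = d·m₁/(m₁+m₃)*. A straight line (isopleth) through a category's
value on *L* and the shared value on *S* crosses *O* exactly at that
category's probability.

The package also builds the companion **scoring chart**: each covariate
effect is standardized to points on a 0–100 scale by the factor
*r = 100 / max_{j,k} |β_jk (x^up_j − x^low_j)|*; per-category baseline
points plus the covariate points give total points, an affine encoding of
the linear predictor (*lp_k = (Total_k + min_k bl_k)/r*), which an
exponentiation axis converts to exp(lp) and thence to the *S*-axis value.

The package computes probabilities from a supplied coefficient table,
derives the chart geometry and the points system, renders both charts as
deterministic SVG with optional case isopleths, and verifies the
geometric reading against the analytic probabilities. It does **not** fit
models — coefficients come from your own multinomial regression fit.

## Worked example

A published antepartum model for the risk of operative delivery ships
with the package: five outcome categories (spontaneous vaginal delivery
as reference; instrumental vaginal delivery or caesarean section, each
due to fetal distress or failure to progress) and seven antepartum
covariates. The hypothetical case is a 32-year-old nulliparous diabetic
woman at 40 weeks' gestation, expecting a boy with an estimated birth
weight of 3540 g:

```r
library(multinomogram)
m <- schuit_model()
category_probabilities(m, schuit_case())
#> Multinomial prediction
#>   linear predictors:
#>  IVD-FD   CS-FD IVD-FTP  CS-FTP
#> -1.4906 -1.8126 -1.7638 -0.6400
#>   s = -0.7358   (sum exp(lp) = 1.0872)
#>   probabilities:
#>      IVD-FD       CS-FD     IVD-FTP      CS-FTP spontaneous
#>      0.1079      0.0782      0.0821      0.2526      0.4791
```

So this subject's predicted risk is about 25% for a caesarean due to
failure to progress and 48% for a spontaneous delivery; the four
non-reference probabilities and the reference probability sum to one.
The scoring-chart route gives the same numbers through points:

```r
chart <- scoring_chart(m)          # r = 27.78 points per log-odds
round(total_points(chart, schuit_case()), 1)
#>  IVD-FD   CS-FD IVD-FTP  CS-FTP
#>   172.4   163.5   164.8   196.1
```

and the charts themselves are plain SVG text:

```r
layout <- nomogram_layout(m)       # axis ranges from the covariate box
case   <- case_reading(chart, schuit_case())
writeLines(render_nomogram(layout, chart, case), "nomogram.svg")
writeLines(render_scoring_chart(chart, case), "chart.svg")
check_model(m)                     # end-to-end geometric verification
```

A command-line wrapper with `predict`, `nomogram`, `chart`, `check` and
`simulate` subcommands is installed at
`system.file("cli", "multinomogram.R", package = "multinomogram")`.

Note: the covariate ranges bundled with the example model are plausible
clinical ranges chosen for this package (the development-data ranges were
not published), so the absolute point values differ from the originally
published chart; the probabilities do not depend on that choice.

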
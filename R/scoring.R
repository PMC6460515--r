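#' Rescaling factor for the standardized points system
#'
#' The points system rescales every coefficient relative to the largest
#' conditional covariate effect over its declared range:
#' \deqn{r = 100 / \max_{j,k} | \beta_{jk} x^{up}_j - \beta_{jk} x^{low}_j |,}
#' so that the largest per-covariate points span is exactly 100 and every
#' span lies in `[0, 100]`. `r` has units of points per log-odds.
#'
#' @param model an [mn_model()].
#' @return Scalar `r > 0`.
#' @export
rescaling_factor <- function(model) {
  span <- abs(sweep(model$beta, 2,
                    model$covariates$upper - model$covariates$lower, "*"))
  m <- max(span)
  if (m == 0)
    stop_mn("all coefficients are zero: the points scale is undefined")
  100 / m
}

#' Build the standardized scoring chart for a model
#'
#' Derives the complete points system: the rescaling factor `r`
#' ([rescaling_factor()]), rescaled coefficients
#' \eqn{\beta^*_{jk} = r \beta_{jk}}, the per-(covariate, category) affine
#' points maps
#' \eqn{Points_{jk}(x) = \beta^*_{jk} x - \min(\beta^*_{jk} x^{up}_j,
#' \beta^*_{jk} x^{low}_j)} (each spanning `[0, span_{jk}]` with
#' `span_{jk} <= 100` and `max span = 100`), baseline scores
#' \eqn{bl_k = r \alpha_k + \sum_j \min(\beta^*_{jk} x^{up}_j,
#' \beta^*_{jk} x^{low}_j)}, their standardized form
#' \eqn{bl^*_k = bl_k - \min_k bl_k} (so \eqn{\min_k bl^*_k = 0}; ties in
#' the minimum need no breaking, the subtraction is well defined), and the
#' achievable total-points range. Total points are an affine encoding of
#' the linear predictor: \eqn{l_k = (Total_k + \min_k bl_k) / r}.
#'
#' @param model an [mn_model()].
#' @return An object of class `"scoring_chart"` with fields `model`, `r`,
#'   `beta_star`, `min_term` and `span` (`(K-1) x J` matrices), `bl`,
#'   `bl_star`, `min_bl`, `total_range` and `exp_range`.
#' @examples
#' chart <- scoring_chart(schuit_model())
#' total_points(chart, schuit_case())
#' @export
scoring_chart <- function(model) {
  findings <- validate_model(model)
  if (length(findings$errors))
    stop_mn("invalid model: %s", paste(findings$errors, collapse = "; "))
  r <- rescaling_factor(model)
  beta_star <- r * model$beta
  bs_lo <- sweep(beta_star, 2, model$covariates$lower, "*")
  bs_up <- sweep(beta_star, 2, model$covariates$upper, "*")
  min_term <- pmin(bs_lo, bs_up)
  span <- pmax(bs_lo, bs_up) - min_term
  bl <- r * model$alpha + rowSums(min_term)
  min_bl <- min(bl)
  bl_star <- bl - min_bl
  # Points_jk is coordinate-wise affine, so per-category totals span
  # [bl_star_k, bl_star_k + sum_j span_jk]; vertices of the covariate box
  # attain both ends
  total_range <- c(min(bl_star), max(bl_star + rowSums(span)))
  structure(
    list(model = model, r = r, beta_star = beta_star,
         min_term = min_term, span = span,
         bl = bl, bl_star = bl_star, min_bl = min_bl,
         total_range = total_range,
         exp_range = exp((total_range + min_bl) / r),
         model_fingerprint = model_fingerprint(model)),
    class = "scoring_chart")
}

#' @export
print.scoring_chart <- function(x, digits = 2, ...) {
  cat("Standardized scoring chart\n")
  cat(sprintf("  rescaling factor r = %g points per log-odds\n", x$r))
  cat("  baseline points bl* (bl):\n")
  for (k in rownames(x$beta_star))
    cat(sprintf("    %-12s %8.*f  (%.*f)\n", k, digits, x$bl_star[k],
                digits, x$bl[k]))
  cat(sprintf("  total points range: [%.*f, %.*f]\n",
              digits, x$total_range[1], digits, x$total_range[2]))
  invisible(x)
}

#' Points awarded by one covariate for one category
#'
#' Evaluates the standardized covariate effect
#' \eqn{Points_{jk}(x) = \beta^*_{jk} x - \min(\beta^*_{jk} x^{up}_j,
#' \beta^*_{jk} x^{low}_j)}. The subtraction anchors the least favorable
#' end of the covariate range at 0 points, so points are non-negative for
#' in-range values regardless of the coefficient's sign; a binary
#' covariate at its favorable level scores 0.
#'
#' @param chart a [scoring_chart()].
#' @param j covariate, by name or index.
#' @param k non-reference category, by name or index.
#' @param x covariate value(s), in covariate units.
#' @param clamp truncate out-of-range values to the covariate range.
#' @return Points in `[0, 100]` (vectorized over `x`).
#' @export
covariate_points <- function(chart, j, k, x, clamp = FALSE) {
  model <- chart$model
  if (is.character(j)) j <- match(j, model$covariates$name)
  if (is.character(k)) k <- match(k, rownames(chart$beta_star))
  if (is.na(j) || is.na(k))
    stop_mn("unknown covariate or category")
  rng <- c(model$covariates$lower[j], model$covariates$upper[j])
  eps <- 1e-9 * max(1, diff(rng))
  out <- x < rng[1] - eps | x > rng[2] + eps
  if (any(out)) {
    if (!clamp)
      stop_mn("covariate value outside the declared range [%g, %g]",
              rng[1], rng[2])
    x <- pmin(pmax(x, rng[1]), rng[2])
  }
  chart$beta_star[k, j] * x - chart$min_term[k, j]
}

# full (K-1) x J points matrix for one aligned profile
points_matrix <- function(chart, profile, clamp = FALSE) {
  x <- align_profile(chart$model, profile, clamp = clamp)
  sweep(chart$beta_star, 2, x, "*") - chart$min_term
}

#' Baseline scores for the points system
#'
#' Computes the category baseline scores
#' \eqn{bl_k = r \alpha_k + \sum_j \min(\beta^*_{jk} x^{up}_j,
#' \beta^*_{jk} x^{low}_j)} and their standardized form
#' \eqn{bl^*_k = bl_k - \min_k bl_k}.
#'
#' @param model an [mn_model()].
#' @param r the rescaling factor; defaults to [rescaling_factor()].
#' @return List with `bl`, `bl_star` (named numeric, one per non-reference
#'   category) and scalar `min_bl`.
#' @export
baselines <- function(model, r = rescaling_factor(model)) {
  beta_star <- r * model$beta
  min_term <- pmin(sweep(beta_star, 2, model$covariates$lower, "*"),
                   sweep(beta_star, 2, model$covariates$upper, "*"))
  bl <- r * model$alpha + rowSums(min_term)
  list(bl = bl, bl_star = bl - min(bl), min_bl = min(bl))
}

#' Total points for a covariate profile
#'
#' \eqn{Total_k = bl^*_k + \sum_j Points_{jk}(x_j)}. Total points encode
#' the linear predictor affinely: \eqn{l_k = (Total_k + \min_k bl_k) / r}.
#'
#' @param chart a [scoring_chart()].
#' @param profile covariate profile (named or positional numeric vector).
#' @param clamp truncate out-of-range values to the declared ranges.
#' @return Named numeric vector of `K - 1` totals.
#' @export
total_points <- function(chart, profile, clamp = FALSE) {
  chart$bl_star + rowSums(points_matrix(chart, profile, clamp = clamp))
}

#' Exponentiated-linear-predictor axis of the scoring chart
#'
#' Maps a total-points value to the exponentiated linear predictor via
#' \eqn{\exp\{(Total + \min_k bl_k)/r\} = e^{l_k}}; these are the values
#' whose sum over categories is the `S`-axis label `g`.
#'
#' @param chart a [scoring_chart()].
#' @param total total points value(s).
#' @param clamp truncate out-of-range totals to the achievable range.
#' @return Exponentiated linear predictor(s).
#' @export
exp_axis_value <- function(chart, total, clamp = FALSE) {
  rng <- chart$total_range
  eps <- 1e-7 * max(1, diff(rng))
  out <- total < rng[1] - eps | total > rng[2] + eps
  if (any(out)) {
    if (!clamp)
      stop_mn("total points outside the achievable range [%g, %g]",
              rng[1], rng[2])
    total <- pmin(pmax(total, rng[1]), rng[2])
  }
  exp((total + chart$min_bl) / chart$r)
}

#' S-axis label value from category totals
#'
#' Sums the exponentiated linear predictors over the non-reference
#' categories: \eqn{g = \sum_k \exp\{(Total_k + \min_k bl_k)/r\}
#' = \sum_k e^{l_k}}. Feeding the result into [s_label_to_s()] recovers
#' the shared term `s` of the nomogram.
#'
#' @param chart a [scoring_chart()].
#' @param totals one total-points value per non-reference category.
#' @param clamp passed to [exp_axis_value()].
#' @return Scalar `g > 0`.
#' @export
chart_S <- function(chart, totals, clamp = FALSE) {
  if (length(totals) != nrow(chart$beta_star))
    stop_mn("expected one total per non-reference category")
  sum(exp_axis_value(chart, totals, clamp = clamp))
}

#' Relabel log-odds as total points
#'
#' Inverse of the total-points identity: `Total = r l - min_k bl_k`. Used
#' to relabel the nomogram's `L` axis in total-points units so chart
#' totals can be marked on it directly. [l_for_total()] is the exact
#' inverse map.
#'
#' @param chart a [scoring_chart()].
#' @param l linear predictor value(s).
#' @param total total points value(s).
#' @return Total points (respectively log-odds).
#' @export
total_label_for_l <- function(chart, l) chart$r * l - chart$min_bl

#' @rdname total_label_for_l
#' @export
l_for_total <- function(chart, total) (total + chart$min_bl) / chart$r

#' Work a case through the scoring chart
#'
#' Produces the full chart reading for one covariate profile: per-covariate
#' points for every non-reference category, total points, exponentiated
#' linear predictors, their sum `S` (the nomogram `S`-axis label), and the
#' probabilities this reading implies. With `integer_points = TRUE` the
#' per-covariate points and baselines are rounded to whole points before
#' summing, reproducing how a printed chart is used by hand; the induced
#' probability error is bounded by `exp((J + 1) * 0.5 / r) - 1`.
#'
#' @param chart a [scoring_chart()].
#' @param profile covariate profile.
#' @param clamp truncate out-of-range values to the declared ranges.
#' @param integer_points round points and baselines to integers before
#'   summing (display-style reading).
#' @return An object of class `"case_reading"`: list with `profile`,
#'   `points` (`(K-1) x J`), `baseline`, `totals`, `l`, `exp_values`, `S`,
#'   `s` and `pi` (probabilities in model category order).
#' @export
case_reading <- function(chart, profile, clamp = FALSE,
                         integer_points = FALSE) {
  x <- align_profile(chart$model, profile, clamp = clamp)
  P <- points_matrix(chart, x)
  baseline <- chart$bl_star
  if (integer_points) {
    P <- round(P)
    baseline <- round(baseline)
  }
  totals <- baseline + rowSums(P)
  l <- l_for_total(chart, totals)
  ev <- exp(l)
  S <- sum(ev)
  model <- chart$model
  pi_by_cat <- c(ev / (1 + S), stats::setNames(1 / (1 + S), model$reference))
  structure(
    list(profile = x, points = P, baseline = baseline, totals = totals,
         l = l, exp_values = ev, S = S, s = -log1p(S),
         pi = pi_by_cat[model$categories],
         integer_points = integer_points),
    class = "case_reading")
}

#' @export
print.case_reading <- function(x, digits = 3, ...) {
  cat("Scoring-chart case reading",
      if (x$integer_points) "(integer points)", "\n")
  tab <- cbind(x$points, baseline = x$baseline, Total = x$totals,
               `exp(l)` = x$exp_values)
  print(round(tab, digits))
  cat(sprintf("  S = sum exp(l) = %.*f\n", digits, x$S))
  cat("  probabilities:\n")
  print(round(x$pi, digits))
  invisible(x)
}
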
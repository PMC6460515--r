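#' Generate a seeded random model specification
#'
#' Draws a reproducible random multinomial logistic model for testing:
#' intercepts from N(0, 1), coefficients from N(0, 0.8), covariates binary
#' with probability `p_binary` (range fixed to `[0, 1]`) and otherwise
#' continuous with a uniform random lower bound in `[-3, 1]` and width in
#' `[0.5, 4]`. The reference category is the last. The global RNG state is
#' left untouched.
#'
#' @param seed integer seed; the same seed always yields the same model.
#' @param K number of outcome categories, `K >= 2`.
#' @param J number of covariates, `J >= 1`.
#' @param p_binary probability that a covariate is binary.
#' @return An [mn_model()].
#' @export
random_model <- function(seed, K = 3, J = 4, p_binary = 0.4) {
  if (K < 2 || J < 1) stop_mn("need K >= 2 and J >= 1")
  with_local_seed(seed, {
    kind <- ifelse(stats::runif(J) < p_binary, "binary", "continuous")
    lower <- ifelse(kind == "binary", 0, stats::runif(J, -3, 1))
    upper <- ifelse(kind == "binary", 1, lower + stats::runif(J, 0.5, 4))
    beta <- matrix(stats::rnorm((K - 1) * J, sd = 0.8), K - 1, J)
    # the points scale needs at least one nonzero effect; a zero draw has
    # probability zero but guard against it anyway
    if (max(abs(beta)) == 0) beta[1, 1] <- 0.5
    mn_model(
      categories = c(paste0("outcome_", seq_len(K - 1)), "reference"),
      covariates = data.frame(
        name = paste0("x", seq_len(J)), kind = kind,
        lower = lower, upper = upper, stringsAsFactors = FALSE),
      intercepts = stats::rnorm(K - 1),
      coefficients = beta)
  })
}

#' Sample random in-range covariate profiles
#'
#' Continuous covariates are drawn uniformly over their declared range,
#' binary covariates as fair coin flips. Uses (and advances) the current
#' RNG state; seed the caller for reproducibility.
#'
#' @param model an [mn_model()].
#' @param n number of profiles.
#' @return Data frame with `n` rows, one column per covariate.
#' @export
random_profiles <- function(model, n = 1) {
  cov <- model$covariates
  cols <- lapply(seq_len(nrow(cov)), function(j) {
    if (cov$kind[j] == "binary") sample(0:1, n, replace = TRUE)
    else stats::runif(n, cov$lower[j], cov$upper[j])
  })
  names(cols) <- cov$name
  as.data.frame(cols, check.names = FALSE)
}

#' End-to-end verification of a model's nomogram and scoring chart
#'
#' Samples random in-range profiles and asserts, for each, the chain of
#' identities the construction relies on: (a) the category probabilities
#' sum to 1 (tolerance `1e-12`); (b) collinearity - the geometric
#' nomogram reading [read_probability()] reproduces each non-reference
#' probability to within `1e-9` relative error; (c) the scoring-chart
#' route (points, totals, exp axis, S label, nomogram read) agrees with
#' the analytic probabilities to within `1e-9`; (d) all points lie in
#' `[0, 100]`.
#'
#' @param model an [mn_model()].
#' @param n_profiles number of random profiles to test.
#' @param seed RNG seed for the profile sample.
#' @param layout,chart optionally, a pre-built [nomogram_layout()] /
#'   [scoring_chart()] to verify instead of freshly built ones (for
#'   negative controls).
#' @return An object of class `"mn_check"`: list with `pass` (logical),
#'   `n_profiles`, `worst` (named numeric worst-case deviations) and
#'   `failures` (up to 10 failing tuples).
#' @export
check_model <- function(model, n_profiles = 100, seed = 1,
                        layout = NULL, chart = NULL) {
  findings <- validate_model(model)
  if (length(findings$errors))
    stop_mn("invalid model: %s", paste(findings$errors, collapse = "; "))
  layout <- layout %||% nomogram_layout(model)
  chart <- chart %||% scoring_chart(model)
  profiles <- with_local_seed(seed, random_profiles(model, n_profiles))
  worst <- c(prob_sum = 0, collinearity = 0, chart_roundtrip = 0,
             points_low = 0, points_high = 0)
  failures <- list()
  fail <- function(i, what, value) {
    if (length(failures) < 10L)
      failures[[length(failures) + 1L]] <<-
        list(profile = i, check = what, deviation = value)
  }
  for (i in seq_len(n_profiles)) {
    x <- profiles[i, , drop = FALSE]
    pred <- category_probabilities(model, x)
    dev <- abs(sum(pred$pi) - 1)
    worst["prob_sum"] <- max(worst["prob_sum"], dev)
    if (dev > 1e-12) fail(i, "probability_sum", dev)

    pi_nonref <- pred$pi[nonref_categories(model)]
    read <- read_probability(layout, pred$l, pred$s, clamp = TRUE)
    dev <- max(abs(read - pi_nonref) / pi_nonref)
    worst["collinearity"] <- max(worst["collinearity"], dev)
    if (dev > 1e-9) fail(i, "collinearity", dev)

    P <- points_matrix(chart, x)
    worst["points_low"] <- min(worst["points_low"], min(P))
    worst["points_high"] <- max(worst["points_high"], max(P))
    if (min(P) < -1e-9 || max(P) > 100 + 1e-9)
      fail(i, "points_bounds", range(P))

    totals <- chart$bl_star + rowSums(P)
    g <- chart_S(chart, totals, clamp = TRUE)
    s_chart <- s_label_to_s(g)
    l_chart <- l_for_total(chart, totals)
    p_chart <- read_probability(layout, l_chart, s_chart, clamp = TRUE)
    dev <- max(abs(p_chart - pi_nonref))
    worst["chart_roundtrip"] <- max(worst["chart_roundtrip"], dev)
    if (dev > 1e-9) fail(i, "chart_roundtrip", dev)
  }
  structure(list(pass = length(failures) == 0L, n_profiles = n_profiles,
                 worst = worst, failures = failures),
            class = "mn_check")
}

#' @export
print.mn_check <- function(x, ...) {
  cat(sprintf("Nomogram verification over %d random profiles: %s\n",
              x$n_profiles, if (x$pass) "PASS" else "FAIL"))
  cat("  worst-case deviations:\n")
  for (nm in names(x$worst))
    cat(sprintf("    %-16s %.3e\n", nm, x$worst[[nm]]))
  for (f in x$failures)
    cat(sprintf("  FAILED %s at profile %d (deviation %s)\n",
                f$check, f$profile, paste(signif(f$deviation, 4),
                                          collapse = ", ")))
  invisible(x)
}
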
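# shared fixtures and independent oracles for the test suite

# two-covariate, three-category model with hand-computable points system:
# r = 50, baselines tie at -100, profile (5, 1) gives totals (100, 125)
toy_model <- function() {
  mn_model(
    categories = c("A", "B", "ref"),
    covariates = data.frame(
      name = c("x1", "x2"), kind = c("continuous", "binary"),
      lower = c(0, 0), upper = c(10, 1), stringsAsFactors = FALSE),
    intercepts = c(-2, -1),
    coefficients = rbind(c(0.2, 1.0), c(-0.1, 2.0)))
}

# hand-checkable geometry: m1 = 2, m3 = 5, m2 = 10/7, d_LO = 20/7
toy_layout <- function() {
  nomogram_layout(h = 10, d = 10, l_range = c(-5, 0), s_range = c(-2, 0))
}

# independent probability oracle: naive term-by-term evaluation, no
# log-sum-exp, ordered non-reference categories first then the reference
oracle_probs <- function(alpha, beta, x) {
  lp <- numeric(length(alpha))
  for (k in seq_along(alpha)) {
    acc <- alpha[k]
    for (j in seq_along(x)) acc <- acc + beta[k, j] * x[j]
    lp[k] <- acc
  }
  denom <- 1 + sum(exp(lp))
  c(exp(lp) / denom, 1 / denom)
}

# deterministic variety of model shapes keyed by seed
seed_shape <- function(seed) {
  list(K = 2L + seed %% 4L, J = 1L + seed %% 5L)
}

# shared collinearity / chart round-trip suite over seeded random models;
# computed once per test run and cached
property_suite <- local({
  cache <- NULL
  function(n = 1000) {
    if (!is.null(cache) && cache$n == n) return(cache)
    worst_col <- 0
    worst_chart <- 0
    for (seed in seq_len(n)) {
      shape <- seed_shape(seed)
      m <- random_model(seed, K = shape$K, J = shape$J)
      layout <- nomogram_layout(m)
      chart <- scoring_chart(m)
      set.seed(seed)
      x <- random_profiles(m, 1)
      pred <- category_probabilities(m, x)
      pi_nonref <- pred$pi[setdiff(m$categories, m$reference)]
      read <- read_probability(layout, pred$l, pred$s, clamp = TRUE)
      worst_col <- max(worst_col, abs(read - pi_nonref) / pi_nonref)
      totals <- total_points(chart, x)
      s_chart <- s_label_to_s(chart_S(chart, totals))
      p_chart <- read_probability(layout, l_for_total(chart, totals),
                                  s_chart, clamp = TRUE)
      worst_chart <- max(worst_chart, abs(p_chart - pi_nonref))
    }
    cache <<- list(n = n, collinearity = worst_col,
                   chart_roundtrip = worst_chart)
    cache
  }
})
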
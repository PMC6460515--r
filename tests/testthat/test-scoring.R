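test_that("the rescaling factor anchors the largest effect at 100 points", {
  m <- toy_model()
  expect_equal(rescaling_factor(m), 50)

  one <- mn_model(categories = c("a", "b"),
                  covariates = data.frame(name = "x", kind = "continuous",
                                          lower = 0, upper = 10),
                  intercepts = 0, coefficients = rbind(10))
  expect_equal(rescaling_factor(one), 1)

  # homogeneity: scaling every coefficient by c scales r by 1/c
  m2 <- mn_model(m$categories, m$covariates, m$alpha, 2 * m$beta)
  expect_equal(rescaling_factor(m2), 25)

  zero <- mn_model(categories = c("a", "b"),
                   covariates = data.frame(name = "x", kind = "continuous",
                                           lower = 0, upper = 1),
                   intercepts = 1, coefficients = rbind(0))
  expect_error(rescaling_factor(zero), "points scale is undefined")
})

test_that("points maps implement the standardization, including negative slopes", {
  chart <- scoring_chart(toy_model())
  expect_equal(covariate_points(chart, "x1", "A", 5), 50)
  expect_equal(covariate_points(chart, "x1", "A", 0), 0)
  # negative coefficient branch: Points = -5x + 50
  expect_equal(covariate_points(chart, "x1", "B", 10), 0)
  expect_equal(covariate_points(chart, "x1", "B", 0), 50)
  # binary covariate at its favorable level scores 0
  expect_equal(covariate_points(chart, "x2", "A", 0), 0)
  expect_equal(covariate_points(chart, "x2", "B", 0), 0)
  expect_error(covariate_points(chart, "x1", "A", 11), "outside")
  expect_equal(covariate_points(chart, "x1", "A", 11, clamp = TRUE), 100)
})

test_that("baselines standardize to a zero minimum, ties included", {
  m <- toy_model()
  b <- baselines(m)
  expect_equal(unname(b$bl), c(-100, -100))
  expect_equal(unname(b$bl_star), c(0, 0))
  expect_equal(b$min_bl, -100)
  # shifting every intercept by c moves bl by r*c and leaves bl* alone
  shifted <- mn_model(m$categories, m$covariates, m$alpha + 0.3, m$beta)
  b2 <- baselines(shifted)
  expect_equal(unname(b2$bl), unname(b$bl) + 50 * 0.3, tolerance = 1e-12)
  expect_equal(b2$bl_star, b$bl_star, tolerance = 1e-12)
})

test_that("total points encode the linear predictor affinely", {
  chart <- scoring_chart(toy_model())
  totals <- total_points(chart, c(x1 = 5, x2 = 1))
  expect_equal(unname(totals), c(100, 125))
  expect_equal(unname(l_for_total(chart, totals)), c(0, 0.5),
               tolerance = 1e-12)
  expect_equal(unname(l_for_total(chart, totals)),
               unname(linear_predictors(toy_model(), c(x1 = 5, x2 = 1))),
               tolerance = 1e-12)
  # a category's total collapses to its baseline at that category's
  # minimum-points profile (which differs per category when signs differ)
  expect_equal(total_points(chart, c(x1 = 0, x2 = 0))[["A"]],
               chart$bl_star[["A"]], tolerance = 1e-12)
  expect_equal(total_points(chart, c(x1 = 10, x2 = 0))[["B"]],
               chart$bl_star[["B"]], tolerance = 1e-12)

  fx <- schuit_model()
  fchart <- scoring_chart(fx)
  ftot <- total_points(fchart, schuit_case())
  expect_equal(unname(l_for_total(fchart, ftot)),
               unname(linear_predictors(fx, schuit_case())),
               tolerance = 1e-10)
})

test_that("the exp axis and S connection reproduce the analytic route", {
  chart <- scoring_chart(toy_model())
  expect_equal(exp_axis_value(chart, 100), 1, tolerance = 1e-12)
  expect_equal(exp_axis_value(chart, 125), exp(0.5), tolerance = 1e-12)
  expect_error(exp_axis_value(chart, 1e6), "outside")

  totals <- total_points(chart, c(x1 = 5, x2 = 1))
  S <- chart_S(chart, totals)
  expect_equal(S, 1 + exp(0.5), tolerance = 1e-12)
  pi_chart <- c(exp_axis_value(chart, totals), 1) / (1 + S)
  expect_equal(round(unname(pi_chart), 4), c(0.2741, 0.4519, 0.2741))
  expect_equal(unname(pi_chart),
               unname(category_probabilities(toy_model(),
                                             c(x1 = 5, x2 = 1))$pi),
               tolerance = 1e-12)
  expect_error(chart_S(chart, 100), "one total per")

  fchart <- scoring_chart(schuit_model())
  ftot <- total_points(fchart, schuit_case())
  fS <- chart_S(fchart, ftot)
  expect_equal(fS, 1.0871514, tolerance = 1e-7)
  expect_equal(s_label_to_s(fS),
               s_value(linear_predictors(schuit_model(), schuit_case())),
               tolerance = 1e-10)
})

test_that("total-points relabeling of the L axis is an exact affine inverse", {
  chart <- scoring_chart(toy_model())
  expect_equal(total_label_for_l(chart, 0), 100)
  set.seed(9)
  l <- rnorm(100, sd = 2)
  expect_equal(l_for_total(chart, total_label_for_l(chart, l)), l,
               tolerance = 1e-12)
})

test_that("points stay in [0, 100] with the largest span exactly 100", {
  for (seed in 1:300) {
    shape <- seed_shape(seed)
    m <- random_model(seed, K = shape$K, J = shape$J)
    chart <- scoring_chart(m)
    expect_gte(min(chart$span), 0)
    expect_lte(max(chart$span), 100 + 1e-9)
    expect_equal(max(chart$span), 100, tolerance = 1e-9)
    expect_equal(min(chart$bl_star), 0)
    set.seed(seed)
    P <- sweep(chart$beta_star, 2, unlist(random_profiles(m, 1)), "*") -
      chart$min_term
    expect_true(all(P >= -1e-9 & P <= 100 + 1e-9))
  }
})

test_that("the chart route is invariant to recentring a covariate", {
  m <- toy_model()
  c0 <- 3
  # x1 -> x1 - 3 with alpha absorbing beta * 3
  m2 <- mn_model(m$categories,
                 data.frame(name = c("x1", "x2"),
                            kind = c("continuous", "binary"),
                            lower = c(-3, 0), upper = c(7, 1),
                            stringsAsFactors = FALSE),
                 m$alpha + m$beta[, "x1"] * c0, m$beta)
  ch1 <- scoring_chart(m)
  ch2 <- scoring_chart(m2)
  expect_equal(ch2$r, ch1$r, tolerance = 1e-12)
  expect_equal(ch2$span, ch1$span, tolerance = 1e-12)
  expect_equal(ch2$bl_star, ch1$bl_star, tolerance = 1e-9)
  x <- c(x1 = 5, x2 = 1)
  x_shift <- c(x1 = 5 - c0, x2 = 1)
  expect_equal(total_points(ch2, x_shift), total_points(ch1, x),
               tolerance = 1e-9)
  expect_equal(unname(category_probabilities(m2, x_shift)$pi),
               unname(category_probabilities(m, x)$pi), tolerance = 1e-12)
})

test_that("integer-rounded readings stay within the propagated error bound", {
  for (seed in 1:50) {
    shape <- seed_shape(seed)
    m <- random_model(seed, K = shape$K, J = shape$J)
    chart <- scoring_chart(m)
    set.seed(seed + 500)
    x <- random_profiles(m, 1)
    exact <- case_reading(chart, x)
    rounded <- case_reading(chart, x, integer_points = TRUE)
    bound <- exp((shape$J + 1) * 0.5 / chart$r) - 1
    expect_lte(max(abs(rounded$pi - exact$pi)), bound)
  }
})
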
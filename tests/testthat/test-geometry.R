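test_that("scaling factors and middle-axis placement follow the construction", {
  lay <- toy_layout()
  expect_equal(lay$m1, 2)
  expect_equal(lay$m3, 5)
  expect_equal(lay$m2, 10 / 7, tolerance = 1e-14)
  expect_equal(lay$d_LO, 20 / 7, tolerance = 1e-14)
  expect_equal(lay$o_low, -7)

  # equal ranges: symmetric placement
  sym <- nomogram_layout(h = 4, d = 8, l_range = c(-3, 1),
                         s_range = c(-4, 0))
  expect_equal(sym$m2, sym$m1 / 2)
  expect_equal(sym$d_LO, 4)
  unit <- nomogram_layout(h = 1, d = 1, l_range = c(0, 1),
                          s_range = c(0, 1))
  expect_equal(c(unit$m1, unit$m3, unit$m2, unit$d_LO), c(1, 1, 0.5, 0.5))

  expect_error(nomogram_layout(h = 0, d = 1, l_range = c(0, 1),
                               s_range = c(0, 1)), "positive")
  expect_error(nomogram_layout(h = 1, d = 1, l_range = c(1, 0),
                               s_range = c(0, 1)), "increasing")
})

test_that("both printed forms of d_LO agree for random scalings", {
  set.seed(42)
  for (i in 1:100) {
    h <- runif(1, 1, 20); d <- runif(1, 1, 20)
    lay <- nomogram_layout(h = h, d = d,
                           l_range = sort(rnorm(2, sd = 4)),
                           s_range = sort(-abs(rnorm(2, sd = 2)) - c(0.1, 0)))
    expect_equal(lay$d_LO, d * lay$m1 / (lay$m1 + lay$m3),
                 tolerance = 1e-12)
  }
})

test_that("axis positions map range ends to 0 and h", {
  lay <- toy_layout()
  expect_equal(position_on_L(lay, -5), 0)
  expect_equal(position_on_L(lay, 0), 10)
  expect_equal(position_on_L(lay, -2), 6)
  expect_equal(position_on_S(lay, -2), 0)
  expect_equal(position_on_S(lay, 0), 10)
  expect_equal(position_on_S(lay, -1), 5)
  expect_equal(position_on_O(lay, exp(lay$o_low)), 0, tolerance = 1e-12)
  # l and s attain their upper bounds jointly at 0, so p = 1 sits at h
  expect_equal(position_on_O(lay, 1), 10, tolerance = 1e-12)
  expect_equal(position_on_O(lay, exp(-3)), 40 / 7, tolerance = 1e-12)

  expect_error(position_on_L(lay, 1), "outside the axis range")
  expect_equal(position_on_L(lay, 1, clamp = TRUE), 10)
  expect_error(position_on_O(lay, 0), "positive")
})

test_that("the S label scale inverts exactly", {
  expect_equal(s_label_to_s(0), 0)
  expect_equal(s_label_to_s(exp(1) - 1), -1, tolerance = 1e-15)
  expect_error(s_label_to_s(-0.1), "non-negative")
  set.seed(7)
  g <- exp(runif(100, -8, 8))
  expect_equal(g_from_s(s_label_to_s(g)), g, tolerance = 1e-12)
  l <- linear_predictors(schuit_model(), schuit_case())
  expect_equal(s_label_to_s(sum(exp(l))), s_value(l), tolerance = 1e-14)
})

test_that("the isopleth intersection reproduces exp(l + s)", {
  lay <- toy_layout()
  expect_equal(read_probability(lay, -2, -1), exp(-3), tolerance = 1e-12)
  expect_equal(read_probability(lay, -5, -2), exp(lay$o_low),
               tolerance = 1e-12)
  m <- schuit_model()
  pred <- category_probabilities(m, schuit_case())
  lay_m <- nomogram_layout(m)
  read <- read_probability(lay_m, pred$l, pred$s)
  expect_equal(unname(read),
               unname(pred$pi[setdiff(m$categories, m$reference)]),
               tolerance = 1e-9)
})

test_that("probability readings are invariant to the choice of h and d", {
  set.seed(11)
  for (i in 1:20) {
    l_range <- sort(rnorm(2, sd = 3))
    s_range <- sort(-abs(rnorm(2, sd = 2)) - c(0.1, 0))
    l <- runif(1, l_range[1], l_range[2])
    s <- runif(1, s_range[1], s_range[2])
    p <- vapply(1:4, function(j) {
      lay <- nomogram_layout(h = runif(1, 1, 30), d = runif(1, 1, 30),
                             l_range = l_range, s_range = s_range)
      read_probability(lay, l, s)
    }, numeric(1))
    expect_equal(max(abs(p / p[1] - 1)), 0, tolerance = 1e-9)
  }
})

test_that("L, S and O points are collinear across random models", {
  suite <- property_suite(200)
  expect_lt(suite$collinearity, 1e-9)
})

test_that("default ranges come from the covariate box", {
  m <- mn_model(categories = c("yes", "no"),
                covariates = data.frame(name = "x", kind = "binary",
                                        lower = 0, upper = 1),
                intercepts = 0, coefficients = rbind(1))
  rng <- default_ranges(m)
  expect_equal(rng$l_range, c(0, 1))
  expect_equal(rng$s_range, c(-log(1 + exp(1)), -log(2)), tolerance = 1e-12)

  zero <- mn_model(categories = c("a", "b"),
                   covariates = data.frame(name = "x", kind = "continuous",
                                           lower = 0, upper = 1),
                   intercepts = 0, coefficients = rbind(0))
  expect_error(default_ranges(zero), "degenerate")

  # every random in-range profile must land inside the derived ranges
  for (seed in c(3, 17, 101)) {
    shape <- seed_shape(seed)
    mm <- random_model(seed, K = shape$K, J = shape$J)
    rng <- default_ranges(mm)
    set.seed(seed)
    X <- random_profiles(mm, 200)
    for (i in seq_len(nrow(X))) {
      pred <- category_probabilities(mm, X[i, ])
      expect_true(all(pred$l >= rng$l_range[1] - 1e-9 &
                        pred$l <= rng$l_range[2] + 1e-9))
      expect_gte(pred$s, rng$s_range[1] - 1e-9)
      expect_lte(pred$s, rng$s_range[2] + 1e-9)
    }
  }
})

test_that("ranges can instead be taken from supplied profiles", {
  m <- toy_model()
  set.seed(5)
  X <- random_profiles(m, 50)
  rng <- default_ranges(m, profiles = X)
  L <- t(apply(X, 1, function(x) linear_predictors(m, x)))
  expect_equal(rng$l_range, range(L), tolerance = 1e-12)
  expect_equal(rng$s_range, range(apply(L, 1, s_value)), tolerance = 1e-12)
  box <- default_ranges(m)
  expect_gte(rng$l_range[1], box$l_range[1] - 1e-9)
  expect_lte(rng$l_range[2], box$l_range[2] + 1e-9)
})

test_that("tick marks are in range, self-consistent and monotone", {
  lay <- nomogram_layout(schuit_model())
  for (axis in c("L", "O", "S")) {
    t <- axis_ticks(lay, axis)
    expect_gt(nrow(t), 2)
    expect_true(all(t$position >= -1e-9 & t$position <= lay$h + 1e-9))
    recomputed <- switch(axis,
      L = position_on_L(lay, t$value, clamp = TRUE),
      S = position_on_S(lay, t$value, clamp = TRUE),
      O = position_on_O(lay, t$value, clamp = TRUE))
    expect_identical(t$position, recomputed)
  }
  # increasing labels climb the L and O axes, descend the S axis
  expect_true(all(diff(axis_ticks(lay, "L")$position) > 0))
  expect_true(all(diff(axis_ticks(lay, "O")$position) > 0))
  s_t <- axis_ticks(lay, "S")
  expect_true(all(diff(as.numeric(s_t$label)) > 0))
  expect_true(all(diff(s_t$position) < 0))
})
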
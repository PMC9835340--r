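test_that("quantile categorization produces reference-coded equal groups", {
  m <- categorize_dummies(1:8, 4)
  expect_equal(dim(m), c(8, 3))  # n_groups - 1 dummies
  expect_equal(unname(m[1, ]), c(0, 0, 0))         # lowest group = reference
  expect_equal(attr(m, "group"), rep(1:4, each = 2))
  expect_true(all(rowSums(m) %in% c(0, 1)))        # partition property

  # one group per distinct value when n_groups equals their count
  m2 <- categorize_dummies(c(10, 20, 30), 3)
  expect_equal(dim(m2), c(3, 2))
  expect_equal(unname(m2), rbind(c(0, 0), c(1, 0), c(0, 1)),
               ignore_attr = TRUE)

  expect_error(categorize_dummies(1:8, 1), ">= 2")
  expect_error(categorize_dummies(rep(1, 10), 3), "distinct")
})

test_that("polynomial terms are plain powers above the linear term", {
  m <- polynomial_terms(c(2, 3), 2)
  expect_equal(unname(m[, 1]), c(4, 9))
  m3 <- polynomial_terms(c(2, 3), 3)
  expect_equal(colnames(m3), c("pow2", "pow3"))
  expect_equal(unname(m3[, 2]), c(8, 27))
  expect_error(polynomial_terms(1:5, 1), ">= 2")

  # the quadratic basis of Z is exactly the generated C column
  d <- generate_dataset(params_joint(100, 0.39, seed = 1))
  expect_identical(unname(polynomial_terms(d$Z, 2)[, 1]), d$C)
})

test_that("linear spline basis is a truncated-power hinge basis", {
  b <- linear_spline_basis(c(0, 1, 2), knots = 1)
  expect_equal(unname(b[, "hinge1"]), c(0, 0, 1))
  # values below every knot have all hinges zero
  b2 <- linear_spline_basis(c(-3, -2, 0, 5), knots = c(1, 2))
  expect_true(all(b2[1:3, c("hinge1", "hinge2")] == 0))
  expect_warning(linear_spline_basis(c(0, 1), knots = 5), "range")

  # recovers a piecewise-linear signal with a slope change at the knot
  set.seed(2)
  x <- runif(2000, -2, 2)
  y <- 1.5 * x + 2 * pmax(x - 0.5, 0) + rnorm(2000, sd = 0.3)
  f <- fit_linear(cbind(1, linear_spline_basis(x, 0.5)), y)
  se <- sqrt(diag(f$covariance))
  expect_lt(abs(f$coefficients["x"] - 1.5), 3 * se["x"])
  expect_lt(abs(f$coefficients["hinge1"] - 2), 3 * se["hinge1"])
})

test_that("restricted cubic spline basis is linear in both tails", {
  # hand value: knots (0,1,2) at x = 1 give (1)^3 / (2-0)^2 = 0.25
  b <- rcs_basis(c(-1, 0, 1), knots = c(0, 1, 2))
  expect_equal(unname(b[3, "rcs1"]), 0.25, tolerance = 1e-12)
  # all non-linear columns vanish at or below the first knot
  expect_equal(unname(b[1:2, "rcs1"]), c(0, 0))

  # zero curvature beyond the last knot: numerical second differences
  grid <- seq(2.5, 6, by = 0.01)
  g <- rcs_basis(grid, knots = c(0, 1, 2))
  for (j in grep("^rcs", colnames(g)))
    expect_lt(max(abs(diff(g[, j], differences = 2))), 1e-8)

  # below the first knot the design (1, x, rcs-terms) is a line: rank 2
  set.seed(3)
  xlow <- runif(50, -5, -1)
  design <- cbind(1, rcs_basis(xlow, knots = c(0, 1, 2)))
  expect_equal(qr(design)$rank, 2)

  expect_error(rcs_basis(1:10, knots = c(0, 1)), "3 knots")
  expect_error(knot_set(c(1, 1, 2)), "strictly increasing")
})

test_that("percentile knot placement follows standard rules", {
  x <- seq(0, 100, by = 0.5)
  k3 <- place_knots(x, 3)
  expect_equal(as.numeric(k3), unname(quantile(x, c(0.1, 0.5, 0.9))),
               tolerance = 1e-10)
  expect_length(place_knots(x, 5), 5)
  expect_error(place_knots(rep(1, 10), 3), "discrete")
})

test_that("basis transforms are deterministic given identical inputs", {
  set.seed(4)
  x <- rnorm(200)
  expect_identical(rcs_basis(x, c(-1, 0, 1)), rcs_basis(x, c(-1, 0, 1)))
  expect_identical(categorize_dummies(x, 4), categorize_dummies(x, 4))
})

test_that("nonlinear-term diagnostic separates linear from quadratic truths", {
  set.seed(5)
  a <- rnorm(10000)
  lin <- assess_linearity(a, 3 * a + rnorm(10000, sd = 0.5))
  expect_s3_class(lin, "linearity_diagnostic")
  expect_identical(lin$verdict, "linear_ok")
  expect_lt(abs(lin$details[["pow2"]]), 0.05)  # ~3 SE of 0 at this n
  expect_true(lin$p_value >= 0 && lin$p_value <= 1)

  quad <- assess_linearity(a, a^2 + rnorm(10000))
  expect_identical(quad$verdict, "nonlinear_suspected")
  expect_lt(abs(quad$details[["pow2"]] - 1), 0.05)
})

test_that("categorical-trend diagnostic exposes a U-shape as non-monotone", {
  set.seed(6)
  a <- rnorm(10000)
  d <- assess_linearity(a, a^2 + rnorm(10000), method = "categorical_trend",
                        n_groups = 4)
  expect_identical(d$verdict, "nonlinear_suspected")
  # E[a^2 | quartile] is symmetric: outer quartiles high, middle low, so
  # the per-category coefficients cannot be monotone increasing
  expect_false(all(diff(c(0, d$details)) > 0))
  # direct conditional-moment oracle: top quartile matches bottom (ref),
  # so its coefficient is near zero while middle ones are negative
  expect_lt(abs(d$details[["group4"]]), 0.1)
  expect_lt(d$details[["group2"]], -0.5)
})

test_that("linearity diagnostics support binary responses via logistic fits", {
  set.seed(7)
  a <- rnorm(5000)
  b <- rbinom(5000, 1, plogis(a^2 - 1))
  d <- assess_linearity(a, b, response_kind = "binary")
  expect_identical(d$verdict, "nonlinear_suspected")
  d2 <- assess_linearity(a, rbinom(5000, 1, plogis(a)),
                         response_kind = "binary",
                         method = "categorical_trend")
  expect_true(d2$p_value >= 0 && d2$p_value <= 1)
  expect_error(assess_linearity(a, rep(1, 5000), response_kind = "binary"),
               "constant")
})
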
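test_that("fit_linear matches exact fits and the normal-equations oracle", {
  # two-point exact fit
  f <- fit_linear(cbind(1, x = c(0, 1)), c(0, 2))
  expect_equal(unname(f$coefficients), c(0, 2), tolerance = 1e-12)

  # noiseless dataset: recovers the generating coefficients
  d <- generate_dataset(sim_params(n = 200, theta1 = 0.39, theta2 = 0.39,
                                   gamma2 = 0.39, gamma3 = 0.39,
                                   sigma = 1e-12, seed = 1))
  design <- cbind(1, X = d$X, Z = d$Z, C = d$C)
  f2 <- fit_linear(design, d$Y)
  expect_equal(unname(f2$coefficients), c(0, 0.59, 0.39, 0.39),
               tolerance = 1e-8)

  # weighted fit equals the direct normal-equations solve
  set.seed(2)
  D <- cbind(1, rnorm(50), runif(50))
  y <- rnorm(50)
  w <- runif(50, 0.5, 2)
  f3 <- fit_linear(D, y, weights = w)
  oracle <- solve(t(D) %*% (w * D), t(D) %*% (w * y))
  expect_equal(unname(f3$coefficients), drop(oracle), tolerance = 1e-10)

  expect_error(fit_linear(D, y[-1]), "disagree")
  expect_error(fit_linear(D, y, weights = -w), "nonnegative")
  expect_warning(fit_linear(cbind(1, a = rep(2, 10)), rnorm(10)),
                 "collinear")
})

test_that("fit_logistic matches the saturated-model oracle and flags separation", {
  # two covariate levels with cell rates 0.25 / 0.75: ML hits the
  # empirical logits, so intercept 0 and slope logit(0.75)
  Z <- rep(c(-1, 1), each = 200)
  x <- c(rep(c(0, 1), c(150, 50)), rep(c(0, 1), c(50, 150)))
  f <- fit_logistic(cbind(1, Z = Z), x)
  expect_true(f$converged)
  expect_equal(unname(f$coefficients), c(0, qlogis(0.75)), tolerance = 1e-6)

  # parameter recovery at large n
  d <- generate_dataset(params_joint(2e4, 0.39, seed = 3))
  f2 <- fit_logistic(cbind(1, Z = d$Z, C = d$C), d$X)
  se <- sqrt(diag(f2$covariance))
  expect_lt(abs(f2$coefficients["Z"] - 0.39), 3 * se["Z"])
  expect_lt(abs(f2$coefficients["C"] - 0.39), 3 * se["C"])

  # degenerate constant exposure is flagged, not silent
  expect_warning(fc <- fit_logistic(cbind(rep(1, 30)), rep(1, 30)),
                 "converge")
  expect_false(fc$converged)
  expect_error(fit_logistic(cbind(1, 1:4), c(0, 1, 2, 1)), "0/1")
})

test_that("propensity scores satisfy the ML score equation and stay in (0,1)", {
  d <- generate_dataset(params_joint(2000, 0.59, seed = 4))
  pr <- estimate_propensity(d, scenario_spec(1))
  expect_true(all(pr$ps > 0 & pr$ps < 1))
  # intercept score equation: mean(ps) == mean(X)
  expect_equal(mean(pr$ps), mean(d$X), tolerance = 1e-8)

  # misspecified (linear-only) propensity model still yields valid scores
  pr_mis <- estimate_propensity(d, scenario_spec(3))
  expect_true(all(pr_mis$ps > 0 & pr_mis$ps < 1))

  # null truth: all scores near 0.5
  d0 <- generate_dataset(sim_params(n = 5000, seed = 5))
  pr0 <- estimate_propensity(d0, model_spec(propensity = ~ Z))
  expect_true(all(abs(pr0$ps - 0.5) < 3 * sqrt(0.25 / 5000) + 0.05))
})

test_that("weight formulas match hand arithmetic and stabilization properties", {
  # unstabilized: exposed 1/PS, unexposed 1/(1-PS)
  w <- compute_weights(c(0.25, 0.25), c(1, 0), stabilized = FALSE)
  expect_equal(w$w, c(4, 1 / 0.75), tolerance = 1e-12)

  # stabilized: exposed p/PS; constructed so p = mean(x) = 0.4
  ws <- compute_weights(c(0.8, rep(0.5, 4)), c(1, 1, 0, 0, 0),
                        stabilized = TRUE)
  expect_equal(ws$p_marginal, 0.4)
  expect_equal(ws$w[1], 0.4 / 0.8, tolerance = 1e-12)  # = 0.5

  # balanced case: all weights exactly 1
  wb <- compute_weights(rep(0.5, 10), rep(c(0, 1), 5), stabilized = TRUE)
  expect_equal(wb$w, rep(1, 10))

  # large-sample stabilization: mean weight near 1, exposed sum near n*p
  d <- generate_dataset(params_joint(1e4, 0.59, seed = 6))
  pr <- estimate_propensity(d, scenario_spec(1))
  wv <- compute_weights(pr$ps, d$X, stabilized = TRUE)
  expect_lt(abs(mean(wv$w) - 1), 0.05)
  p <- mean(d$X)
  n1 <- sum(d$X == 1)
  expect_lt(abs(sum(wv$w[d$X == 1]) - 1e4 * p),
            3 * sqrt(n1) * stats::sd(wv$w[d$X == 1]))

  expect_error(compute_weights(c(0, 0.5), c(1, 0)), "inside")
  expect_error(compute_weights(c(0.5, 0.5), c(1, 2)), "0/1")
})

test_that("all four estimators are exact on noiseless data under correct specification", {
  # gamma2 = gamma3 = 0 so the outcome lies in every method's model span
  d <- generate_dataset(sim_params(n = 400, theta1 = 0.59, theta2 = 0.59,
                                   gamma2 = 0, gamma3 = 0, sigma = 1e-12,
                                   seed = 7))
  fits <- adjust_effect(Y ~ X, d, method = "all")
  for (f in fits) expect_lt(abs(f$beta1 - 0.59), 1e-8)

  # multivariable and DR are exact even with full quadratic confounding
  d2 <- generate_dataset(params_joint(400, 0.59, seed = 8, sigma = 1e-12))
  expect_lt(abs(adjust_multivariable(d2, scenario_spec(1))$beta1 - 0.59), 1e-8)
  expect_lt(abs(adjust_dr(d2, scenario_spec(1))$beta1 - 0.59), 1e-8)
})

test_that("IPW with unit weights reproduces the unadjusted mean difference", {
  d <- generate_dataset(params_joint(500, 0.59, seed = 9))
  f <- fit_linear(cbind(1, X = d$X), d$Y, weights = rep(1, 500))
  unadj <- mean(d$Y[d$X == 1]) - mean(d$Y[d$X == 0])
  expect_equal(unname(f$coefficients["X"]), unadj, tolerance = 1e-10)
})

test_that("a degenerate constant propensity score collapses to the unadjusted difference", {
  d <- generate_dataset(sim_params(n = 300, seed = 10))
  # intercept-only propensity model: PS constant, dropped as collinear
  expect_warning(
    est <- adjust_ps_covariate(d, model_spec(propensity = ~ 1)),
    "collinear")
  unadj <- mean(d$Y[d$X == 1]) - mean(d$Y[d$X == 0])
  expect_equal(est$beta1, unadj, tolerance = 1e-10)
})

test_that("estimates are location-invariant and scale-equivariant in the outcome", {
  d <- generate_dataset(params_joint(400, 0.39, seed = 11))
  base <- suppressWarnings(adjust_effect(Y ~ X, d, method = "all"))
  shifted <- d; shifted$Y <- shifted$Y + 10
  scaled <- d; scaled$Y <- scaled$Y * -2.5
  fs <- suppressWarnings(adjust_effect(Y ~ X, shifted, method = "all"))
  fc <- suppressWarnings(adjust_effect(Y ~ X, scaled, method = "all"))
  for (m in names(base)) {
    expect_equal(fs[[m]]$beta1, base[[m]]$beta1, tolerance = 1e-10)
    expect_equal(fc[[m]]$beta1, -2.5 * base[[m]]$beta1, tolerance = 1e-10)
  }
})

test_that("double-robust bias shrinks with sample size under single misspecification", {
  bias_at <- function(n, scenario, reps) {
    sp <- condition_spec(scenario, n = n, effect_size = 0.59, reps = reps,
                         master_seed = 100, methods = "dr")
    run_condition(sp)$ab
  }
  ns <- c(500, 2000, 10000)
  reps <- c(200, 150, 60)
  # correct PS, wrong outcome model (finite-sample weighting bias)
  b2 <- mapply(bias_at, ns, reps, MoreArgs = list(scenario = 2))
  expect_lt(b2[3], b2[1])
  expect_lt(b2[2], b2[1])
  # wrong PS, correct outcome model: double robustness keeps bias small
  b3 <- mapply(bias_at, ns, reps, MoreArgs = list(scenario = 3))
  expect_lt(b3[3], 0.02)
  expect_lt(b3[1], 0.05)
})

test_that("effect_estimate objects behave like model fits", {
  d <- generate_dataset(params_joint(300, 0.39, seed = 12))
  f <- adjust_effect(Y ~ X, d, method = "multivariable")
  expect_s3_class(f, "effect_estimate")
  expect_true(f$ci_low <= f$beta1 && f$beta1 <= f$ci_high)
  expect_named(coef(f), "exposure")
  ci <- confint(f)
  expect_equal(unname(ci[1, ]), c(f$ci_low, f$ci_high), tolerance = 1e-10)
  expect_length(residuals(f), 300)
  expect_output(print(f), "Multivariable")
  s <- summary(f)
  expect_equal(s$beta1, f$beta1)
})
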
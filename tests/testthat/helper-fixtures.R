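# Shared fixtures built in code.

# Default-style parameter set with joint effect size `e` on both
# confounder associations.
params_joint <- function(n, e, seed, gamma1 = 0.59, sigma = 1) {
  sim_params(n = n, theta1 = e, theta2 = e, gamma1 = gamma1,
             gamma2 = e, gamma3 = e, sigma = sigma, seed = seed)
}

# Analysis-mode dataset with a single quadratically confounding variable
# named A (truth: exposure effect 0.59).
quadratic_confounding_data <- function(n = 1500, seed = 11) {
  set.seed(seed)
  A <- rnorm(n)
  X <- rbinom(n, 1, plogis(0.59 * A + 0.59 * A^2))
  Y <- 0.59 * X + 0.59 * A + 0.59 * A^2 + rnorm(n)
  data.frame(A = A, X = X, Y = Y)
}
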
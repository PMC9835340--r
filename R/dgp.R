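#' Parameters of the simulation data-generating process
#'
#' Bundles the full parameterization of the synthetic data-generating
#' process used throughout the simulation engine.  A single standard-normal
#' confounder `Z` and its square `C = Z^2` confound the effect of a binary
#' exposure `X` on a continuous outcome `Y`:
#'
#' \deqn{P(X = 1 \mid Z, C) = \mathrm{logit}^{-1}(i_4 + \theta_1 Z + \theta_2 C)}
#' \deqn{Y = i_5 + \gamma_1 X + \gamma_2 Z + \gamma_3 C + \varepsilon,\qquad
#'       \varepsilon \sim N(0, \sigma^2)}
#'
#' Because both the exposure and the outcome depend on `C = Z^2`, the
#' confounder has a quadratic relation with both; an analysis that adjusts
#' for `Z` alone misspecifies the functional form.
#'
#' @param n Sample size (positive integer).
#' @param theta1,theta2 Confounder-exposure log-odds coefficients on `Z`
#'   and `C`.
#' @param gamma1 True exposure effect on the outcome (default 0.59, a
#'   large standardized effect).
#' @param gamma2,gamma3 Confounder-outcome coefficients on `Z` and `C`.
#' @param i4 Intercept of the exposure model (default 0, giving exposure
#'   prevalence near 0.5 when the coefficients are small).
#' @param i5 Intercept of the outcome model (default 0).
#' @param sigma Standard deviation of the outcome noise (default 1).
#' @param seed Integer seed making the generated dataset reproducible.
#' @return An object of class `sim_params` (a validated list).
#' @seealso [generate_dataset()]
#' @examples
#' p <- sim_params(n = 500, theta1 = 0.59, theta2 = 0.59,
#'                 gamma2 = 0.59, gamma3 = 0.59, seed = 1)
#' d <- generate_dataset(p)
#' head(d)
#' @export
sim_params <- function(n, theta1 = 0, theta2 = 0, gamma1 = 0.59,
                       gamma2 = 0, gamma3 = 0, i4 = 0, i5 = 0,
                       sigma = 1, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("`sigma` must be a positive number", call. = FALSE)
  for (nm in c("theta1", "theta2", "gamma1", "gamma2", "gamma3", "i4", "i5"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L || is.na(get(nm)))
      stop(sprintf("`%s` must be a single number", nm), call. = FALSE)
  structure(list(n = as.integer(n), theta1 = theta1, theta2 = theta2,
                 gamma1 = gamma1, gamma2 = gamma2, gamma3 = gamma3,
                 i4 = i4, i5 = i5, sigma = sigma, seed = as.integer(seed)),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Simulation parameters (n =", x$n, ", seed =", x$seed, ")\n")
  cat(sprintf("  exposure model:  logit P(X=1) = %g + %g Z + %g C\n",
              x$i4, x$theta1, x$theta2))
  cat(sprintf("  outcome model:   Y = %g + %g X + %g Z + %g C + N(0, %g^2)\n",
              x$i5, x$gamma1, x$gamma2, x$gamma3, x$sigma))
  invisible(x)
}

#' Draw the confounder pair (Z, C = Z^2)
#'
#' `Z` is drawn i.i.d. standard normal and `C` is its elementwise square,
#' so `C[i] == Z[i]^2` holds exactly.  Uses the current R random-number
#' state; call [set.seed()] (or use [generate_dataset()]) for
#' reproducibility.
#'
#' @param n Number of subjects (positive integer).
#' @return A list with numeric vectors `Z` and `C`, each of length `n`.
#' @export
generate_confounders <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a positive integer", call. = FALSE)
  Z <- stats::rnorm(n)
  list(Z = Z, C = Z^2)
}

#' Draw the binary exposure from the logistic exposure model
#'
#' Each subject's exposure is Bernoulli with success probability
#' `plogis(i4 + theta1 * Z + theta2 * C)`.
#'
#' @param Z,C Confounder vectors of equal length (`C` is the squared
#'   confounder).
#' @param params A [sim_params()] object supplying `i4`, `theta1`, `theta2`.
#' @return An integer 0/1 vector of the same length as `Z`.
#' @export
generate_exposure <- function(Z, C, params) {
  if (length(Z) != length(C))
    stop("`Z` and `C` must have the same length", call. = FALSE)
  p <- stats::plogis(params$i4 + params$theta1 * Z + params$theta2 * C)
  stats::rbinom(length(Z), 1L, p)
}

#' Draw the continuous outcome from the linear outcome model
#'
#' `Y = i5 + gamma1 * X + gamma2 * Z + gamma3 * C + eps` with
#' `eps ~ N(0, sigma^2)`.
#'
#' @param X Binary exposure vector.
#' @param Z,C Confounder vectors.
#' @param params A [sim_params()] object supplying the gammas, `i5`, `sigma`.
#' @return A numeric vector of outcomes.
#' @export
generate_outcome <- function(X, Z, C, params) {
  nn <- length(X)
  if (length(Z) != nn || length(C) != nn)
    stop("`X`, `Z` and `C` must have the same length", call. = FALSE)
  if (params$sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  params$i5 + params$gamma1 * X + params$gamma2 * Z + params$gamma3 * C +
    stats::rnorm(nn, 0, params$sigma)
}

#' Generate a complete synthetic dataset
#'
#' Chains [generate_confounders()], [generate_exposure()] and
#' [generate_outcome()] under the seed carried by `params`; the result is
#' bit-reproducible given the same parameters.
#'
#' @param params A [sim_params()] object.
#' @return A `data.frame` with columns `Z`, `C`, `X`, `Y` and the
#'   parameters attached as attribute `"params"`.
#' @examples
#' d <- generate_dataset(sim_params(n = 200, theta1 = 0.39, theta2 = 0.39,
#'                                  gamma2 = 0.39, gamma3 = 0.39, seed = 7))
#' stopifnot(identical(d$C, d$Z^2))
#' @export
generate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  zc <- generate_confounders(params$n)
  X <- generate_exposure(zc$Z, zc$C, params)
  Y <- generate_outcome(X, zc$Z, zc$C, params)
  out <- data.frame(Z = zc$Z, C = zc$C, X = X, Y = Y)
  attr(out, "params") <- params
  out
}
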
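# Building blocks for the four confounder-adjustment estimators: design
# construction from term formulas, (weighted) linear and logistic fits,
# propensity scores and inverse-probability weights.

#' Model specification for confounder adjustment
#'
#' Pairs the two term sets that drive every estimator: the confounder part
#' of the outcome model and the confounder part of the propensity (exposure)
#' model.  Each is a one-sided formula evaluated in `data`, so flexible
#' bases such as [rcs()], [lspline()], [dummy()] or [stats::poly()] can be
#' used directly, e.g. `model_spec(outcome = ~ rcs(Z, 3), propensity = ~ Z)`.
#'
#' @param outcome One-sided formula for the confounder terms of the
#'   outcome model.
#' @param propensity One-sided formula for the confounder terms of the
#'   propensity model.
#' @param exposure,outcome_col Names of the exposure and outcome columns
#'   (defaults `"X"` and `"Y"`, the synthetic-data layout).
#' @return An object of class `model_spec`.
#' @seealso [scenario_spec()] for the four canonical
#'   (mis)specification scenarios.
#' @export
model_spec <- function(outcome = ~ Z + C, propensity = ~ Z + C,
                       exposure = "X", outcome_col = "Y") {
  stopifnot(inherits(outcome, "formula"), inherits(propensity, "formula"))
  if (length(outcome) != 2L || length(propensity) != 2L)
    stop("`outcome` and `propensity` must be one-sided formulas",
         call. = FALSE)
  structure(list(outcome = outcome, propensity = propensity,
                 exposure = exposure, outcome_col = outcome_col),
            class = "model_spec")
}

#' Canonical specification scenarios
#'
#' The four combinations of correctly specifying (`~ Z + C`) or
#' misspecifying as linear (`~ Z`) the confounder-exposure and the
#' confounder-outcome association:
#'
#' | scenario | propensity terms | outcome terms |
#' |----------|------------------|---------------|
#' | 1        | `Z + C` (correct)  | `Z + C` (correct) |
#' | 2        | `Z + C` (correct)  | `Z` (misspecified) |
#' | 3        | `Z` (misspecified) | `Z + C` (correct) |
#' | 4        | `Z` (misspecified) | `Z` (misspecified) |
#'
#' @param scenario Integer 1--4.
#' @return A [model_spec()].
#' @export
scenario_spec <- function(scenario) {
  if (!scenario %in% 1:4)
    stop("`scenario` must be 1, 2, 3 or 4", call. = FALSE)
  correct <- ~ Z + C
  linear <- ~ Z
  environment(correct) <- environment(linear) <- asNamespace("confbias")
  switch(scenario,
         model_spec(outcome = correct, propensity = correct),
         model_spec(outcome = linear, propensity = correct),
         model_spec(outcome = correct, propensity = linear),
         model_spec(outcome = linear, propensity = linear))
}

# Design matrix (with intercept) from a one-sided term formula.
build_design <- function(terms_formula, data) {
  stats::model.matrix(terms_formula, data)
}

# Drop rank-deficient columns (never `protect`ed ones) with a warning.
drop_collinear <- function(design, protect = character()) {
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    drop <- qrd$pivot[(qrd$rank + 1L):ncol(design)]
    bad <- intersect(colnames(design)[drop], protect)
    if (length(bad))
      stop("column(s) ", paste(bad, collapse = ", "),
           " cannot be dropped but are collinear", call. = FALSE)
    warning("dropping constant/collinear column(s): ",
            paste(colnames(design)[drop], collapse = ", "), call. = FALSE)
    design <- design[, -drop, drop = FALSE]
  }
  design
}

#' Weighted least-squares fit on an explicit design matrix
#'
#' Minimizes the (weighted) residual sum of squares.  The covariance is
#' the classical OLS estimate \eqn{\hat\sigma^2 (D'D)^{-1}} for unweighted
#' fits and the heteroskedasticity-robust HC0 sandwich (via
#' \pkg{sandwich}) when weights are supplied, the appropriate choice for
#' inverse-probability-weighted estimators.  Constant or collinear
#' columns are dropped with a warning rather than failing.
#'
#' @param design Numeric matrix including an intercept column.
#' @param y Numeric response vector.
#' @param weights Optional positive case weights.
#' @return A list of class `fit_result` with `coefficients`,
#'   `covariance`, `n_obs`, `converged`, `residuals`, `fitted` and the
#'   underlying `lm` object.
#' @export
fit_linear <- function(design, y, weights = NULL) {
  if (!is.matrix(design)) design <- as.matrix(design)
  if (nrow(design) != length(y))
    stop("`design` and `y` dimensions disagree", call. = FALSE)
  if (!is.null(weights)) {
    if (length(weights) != length(y) || any(!is.finite(weights)) ||
        any(weights < 0))
      stop("`weights` must be nonnegative, finite and match `y`",
           call. = FALSE)
  }
  design <- drop_collinear(design)
  fit <- stats::lm(y ~ design - 1, weights = weights)
  cf <- stats::coef(fit)
  names(cf) <- colnames(design)
  vc <- if (is.null(weights)) stats::vcov(fit)
        else sandwich::vcovHC(fit, type = "HC0")
  dimnames(vc) <- list(colnames(design), colnames(design))
  structure(list(coefficients = cf, covariance = vc,
                 n_obs = length(y), converged = TRUE,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit), lm = fit),
            class = "fit_result")
}

#' Maximum-likelihood logistic fit on an explicit design matrix
#'
#' Fits by iteratively reweighted least squares (via [stats::glm()];
#' convergence tolerance 1e-8, at most 100 iterations).  Complete or
#' quasi-complete separation — fitted probabilities pinned at 0/1, or a
#' degenerate constant response — is reported through `converged = FALSE`
#' with a warning, never as silent success.
#'
#' @param design Numeric matrix including an intercept column.
#' @param x Binary 0/1 response (the exposure).
#' @return A `fit_result` list; `converged` is `FALSE` on separation or
#'   IRLS non-convergence.
#' @export
fit_logistic <- function(design, x) {
  if (!is.matrix(design)) design <- as.matrix(design)
  if (nrow(design) != length(x))
    stop("`design` and `x` dimensions disagree", call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop("`x` must be coded 0/1", call. = FALSE)
  design <- drop_collinear(design)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(design, x, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  converged <- isTRUE(fit$converged) && !separated && !isTRUE(fit$boundary) &&
    length(unique(x)) > 1L
  if (!converged)
    warning("logistic fit did not converge cleanly ",
            "(possible separation or degenerate exposure)", call. = FALSE)
  cf <- fit$coefficients
  names(cf) <- colnames(design)
  # observed-information covariance from the final IRLS weights
  w <- fit$weights
  xtwx <- crossprod(design * sqrt(w))
  vc <- tryCatch(solve(xtwx), error = function(e) {
    matrix(NA_real_, ncol(design), ncol(design))
  })
  dimnames(vc) <- list(colnames(design), colnames(design))
  structure(list(coefficients = cf, covariance = vc,
                 n_obs = length(x), converged = converged,
                 fitted = fit$fitted.values,
                 residuals = x - fit$fitted.values),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Fit (n =", x$n_obs,
      if (!x$converged) ", NOT converged" else "", ")\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Estimate propensity scores
#'
#' Fits the logistic propensity model given by `spec$propensity` and
#' returns each subject's predicted probability of exposure.  Predicted
#' probabilities are clipped into `[1e-10, 1 - 1e-10]` purely for
#' numerical safety; no weight trimming is applied anywhere downstream.
#'
#' @param data A data frame containing the exposure and confounders.
#' @param spec A [model_spec()].
#' @return A list of class `propensity_result` with the logistic
#'   `fit` and the clipped propensity score vector `ps`.
#' @export
estimate_propensity <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  design <- build_design(spec$propensity, data)
  fit <- fit_logistic(design, data[[spec$exposure]])
  ps <- pmin(pmax(fit$fitted, 1e-10), 1 - 1e-10)
  structure(list(fit = fit, ps = ps), class = "propensity_result")
}

#' Inverse-probability-of-exposure weights
#'
#' Unstabilized weights are `1/PS` for exposed and `1/(1 - PS)` for
#' unexposed subjects.  Stabilized weights multiply these by the marginal
#' exposure probability: `p/PS` for exposed and `(1 - p)/(1 - PS)` for
#' unexposed, with `p` estimated as the sample proportion exposed.
#' Stabilization shrinks extreme weights and gives mean weight near 1 in
#' large samples.
#'
#' @param ps Propensity scores, strictly inside (0, 1).
#' @param x Binary 0/1 exposure vector.
#' @param stabilized Use stabilized weights? (default `TRUE`).
#' @return A list of class `weight_vector` with fields `w`, `stabilized`
#'   and `p_marginal`.
#' @examples
#' compute_weights(ps = c(0.25, 0.25), x = c(1, 0), stabilized = FALSE)$w
#' @export
compute_weights <- function(ps, x, stabilized = TRUE) {
  if (length(ps) != length(x))
    stop("`ps` and `x` must have the same length", call. = FALSE)
  if (any(ps <= 0) || any(ps >= 1))
    stop("propensity scores must lie strictly inside (0, 1)", call. = FALSE)
  if (!all(x %in% c(0, 1)))
    stop("`x` must be coded 0/1", call. = FALSE)
  p <- mean(x)
  w <- if (stabilized) ifelse(x == 1, p / ps, (1 - p) / (1 - ps))
       else ifelse(x == 1, 1 / ps, 1 / (1 - ps))
  if (any(!is.finite(w)) || any(w <= 0))
    stop("non-finite or non-positive weights produced", call. = FALSE)
  structure(list(w = w, stabilized = stabilized, p_marginal = p),
            class = "weight_vector")
}

# ---- the four confounder-adjustment estimators -------------------------

new_effect_estimate <- function(method, fit, exposure, converged = TRUE,
                                propensity = NULL, weights = NULL) {
  beta1 <- unname(fit$coefficients[exposure])
  se <- sqrt(fit$covariance[exposure, exposure])
  z <- stats::qnorm(0.975)
  structure(list(method = method, beta1 = beta1, se = se,
                 ci_low = beta1 - z * se, ci_high = beta1 + z * se,
                 converged = converged, n_obs = fit$n_obs,
                 outcome_fit = fit, propensity = propensity,
                 weights = weights),
            class = "effect_estimate")
}

outcome_design <- function(data, spec, extra = NULL) {
  X <- data[[spec$exposure]]
  if (!all(X %in% c(0, 1)))
    stop("exposure column must be coded 0/1", call. = FALSE)
  base <- cbind(`(Intercept)` = rep(1, nrow(data)), X = X)
  colnames(base)[2] <- spec$exposure
  if (!is.null(extra)) base <- cbind(base, extra)
  base
}

#' Multivariable regression adjustment
#'
#' Regresses the outcome on the exposure and the confounder terms of
#' `spec$outcome`; the exposure coefficient is the adjusted effect.  Only
#' the confounder-outcome association must be correctly specified for
#' this estimator to be unbiased.
#'
#' @param data A data frame with exposure, outcome and confounders.
#' @param spec A [model_spec()].
#' @return An object of class `effect_estimate`.
#' @export
adjust_multivariable <- function(data, spec = model_spec()) {
  mm <- build_design(spec$outcome, data)
  design <- outcome_design(data, spec, mm[, -1, drop = FALSE])
  fit <- fit_linear(design, data[[spec$outcome_col]])
  new_effect_estimate("multivariable", fit, spec$exposure)
}

#' Covariate adjustment using the propensity score
#'
#' Regresses the outcome on the exposure and the propensity score.  Both
#' the propensity model and the (assumed linear) PS-outcome association
#' must be correctly specified for unbiasedness.
#'
#' @inheritParams adjust_multivariable
#' @param ps_transform Function applied to the PS before it enters the
#'   outcome model (default identity).
#' @return An object of class `effect_estimate`.
#' @export
adjust_ps_covariate <- function(data, spec = model_spec(),
                                ps_transform = identity) {
  pr <- estimate_propensity(data, spec)
  design <- outcome_design(data, spec, cbind(PS = ps_transform(pr$ps)))
  fit <- fit_linear(design, data[[spec$outcome_col]])
  new_effect_estimate("ps_covariate", fit, spec$exposure,
                      converged = pr$fit$converged, propensity = pr)
}

#' Inverse probability weighting
#'
#' Weights each subject by the inverse probability of the exposure level
#' actually received (stabilized by default) and regresses the outcome on
#' the exposure alone in the weighted pseudo-population.  Only the
#' propensity model must be correctly specified.  A warning is issued
#' when the largest weight exceeds 10 times the 99th-percentile weight, a
#' symptom of unstable weights.
#'
#' @inheritParams adjust_multivariable
#' @param stabilized Use stabilized weights? (default `TRUE`).
#' @return An object of class `effect_estimate`.
#' @export
adjust_ipw <- function(data, spec = model_spec(), stabilized = TRUE) {
  pr <- estimate_propensity(data, spec)
  wv <- compute_weights(pr$ps, data[[spec$exposure]], stabilized)
  if (max(wv$w) > 10 * stats::quantile(wv$w, 0.99))
    warning("extreme inverse-probability weights detected ",
            "(max > 10 x 99th percentile); estimate may be unstable",
            call. = FALSE)
  design <- outcome_design(data, spec)
  fit <- fit_linear(design, data[[spec$outcome_col]], weights = wv$w)
  new_effect_estimate("ipw", fit, spec$exposure,
                      converged = pr$fit$converged, propensity = pr,
                      weights = wv)
}

#' Double-robust estimation
#'
#' Combines the two single-model approaches: stabilized
#' inverse-probability weights from the propensity model, then a weighted
#' regression of the outcome on the exposure and the confounder terms.
#' The estimator is consistent if either the propensity model or the
#' outcome model is correctly specified.
#'
#' @inheritParams adjust_multivariable
#' @return An object of class `effect_estimate`.
#' @export
adjust_dr <- function(data, spec = model_spec()) {
  pr <- estimate_propensity(data, spec)
  wv <- compute_weights(pr$ps, data[[spec$exposure]], stabilized = TRUE)
  mm <- build_design(spec$outcome, data)
  design <- outcome_design(data, spec, mm[, -1, drop = FALSE])
  fit <- fit_linear(design, data[[spec$outcome_col]], weights = wv$w)
  new_effect_estimate("dr", fit, spec$exposure,
                      converged = pr$fit$converged, propensity = pr,
                      weights = wv)
}
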
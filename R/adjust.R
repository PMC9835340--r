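#' Confounder-adjusted exposure-effect estimation
#'
#' The central fitting function: estimates the effect of a binary
#' exposure on a continuous outcome, adjusted for confounding by one of
#' four methods — multivariable regression (`"multivariable"`), covariate
#' adjustment using the propensity score (`"ps_covariate"`), (stabilized)
#' inverse probability weighting (`"ipw"`) or double-robust estimation
#' (`"dr"`) — or all four at once (`"all"`).
#'
#' The main formula names the outcome and the exposure
#' (`outcome ~ exposure`); the confounder functional forms are given as
#' one-sided formulas, where flexible bases such as [rcs()], [lspline()]
#' or [dummy()] model non-linear confounder-exposure and
#' confounder-outcome associations.  Misspecifying a truly non-linear
#' association as linear biases the estimate for any method that uses the
#' affected model (see [scenario_spec()] and [run_grid()]).
#'
#' @param formula Two-sided formula `outcome ~ exposure`; the exposure
#'   must be a single 0/1 column of `data`.
#' @param data A data frame.
#' @param outcome_terms One-sided formula of confounder terms for the
#'   outcome model (used by `"multivariable"` and `"dr"`).
#' @param propensity_terms One-sided formula of confounder terms for the
#'   propensity model (used by `"ps_covariate"`, `"ipw"` and `"dr"`).
#' @param method One of `"multivariable"`, `"ps_covariate"`, `"ipw"`,
#'   `"dr"`, or `"all"`.
#' @param stabilized Use stabilized weights for IPW? (default `TRUE`).
#' @return For a single method, an object of class `effect_estimate`;
#'   for `"all"`, a named list of them (class `effect_estimate_list`).
#' @examples
#' d <- generate_dataset(sim_params(n = 400, theta1 = 0.59, theta2 = 0.59,
#'                                  gamma2 = 0.59, gamma3 = 0.59, seed = 3))
#' adjust_effect(Y ~ X, d, outcome_terms = ~ Z + C,
#'               propensity_terms = ~ Z + C, method = "dr")
#' @export
adjust_effect <- function(formula, data, outcome_terms = ~ Z + C,
                          propensity_terms = ~ Z + C,
                          method = c("multivariable", "ps_covariate",
                                     "ipw", "dr", "all"),
                          stabilized = TRUE) {
  method <- match.arg(method)
  if (length(formula) != 3L)
    stop("`formula` must be two-sided: outcome ~ exposure", call. = FALSE)
  ycol <- all.vars(formula[[2]])
  xcol <- all.vars(formula[[3]])
  if (length(ycol) != 1L || length(xcol) != 1L)
    stop("`formula` must name exactly one outcome and one exposure column",
         call. = FALSE)
  missing_cols <- setdiff(c(ycol, xcol), names(data))
  if (length(missing_cols))
    stop("column(s) not in `data`: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  spec <- model_spec(outcome = outcome_terms, propensity = propensity_terms,
                     exposure = xcol, outcome_col = ycol)
  if (method == "all") {
    out <- list(
      multivariable = adjust_multivariable(data, spec),
      ps_covariate = adjust_ps_covariate(data, spec),
      ipw = adjust_ipw(data, spec, stabilized = stabilized),
      dr = adjust_dr(data, spec))
    class(out) <- "effect_estimate_list"
    return(out)
  }
  switch(method,
         multivariable = adjust_multivariable(data, spec),
         ps_covariate = adjust_ps_covariate(data, spec),
         ipw = adjust_ipw(data, spec, stabilized = stabilized),
         dr = adjust_dr(data, spec))
}

method_label <- function(method) {
  c(multivariable = "Multivariable regression analysis",
    ps_covariate = "Covariate adjustment using the PS",
    ipw = "Stabilized IPW",
    dr = "DR estimation")[[method]]
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  cat(method_label(x$method), "\n")
  cat(sprintf("  exposure effect: %.*f  (SE %.*f, 95%% CI %.*f to %.*f)\n",
              digits, x$beta1, digits, x$se,
              digits, x$ci_low, digits, x$ci_high))
  if (!x$converged)
    cat("  note: underlying propensity/logistic fit did not converge\n")
  invisible(x)
}

#' @export
summary.effect_estimate <- function(object, ...) {
  out <- data.frame(method = object$method, beta1 = object$beta1,
                    se = object$se, ci_low = object$ci_low,
                    ci_high = object$ci_high, n_obs = object$n_obs,
                    converged = object$converged)
  class(out) <- c("summary.effect_estimate", "data.frame")
  out
}

#' @export
coef.effect_estimate <- function(object, ...) {
  c(exposure = object$beta1)
}

#' @export
confint.effect_estimate <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(object$beta1 - z * object$se,
                object$beta1 + z * object$se), nrow = 1,
              dimnames = list("exposure",
                              sprintf("%.1f %%", c((1 - level) / 2,
                                                   1 - (1 - level) / 2) * 100)))
  m
}

#' @export
vcov.effect_estimate <- function(object, ...) {
  object$outcome_fit$covariance
}

#' @export
residuals.effect_estimate <- function(object, ...) {
  object$outcome_fit$residuals
}

#' @export
print.effect_estimate_list <- function(x, ...) {
  for (e in x) print(e, ...)
  invisible(x)
}

#' @export
summary.effect_estimate_list <- function(object, ...) {
  do.call(rbind, lapply(object, summary))
}
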
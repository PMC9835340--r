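# Flexible functional-form bases: quantile categorization, polynomial
# terms, linear splines and restricted cubic splines, plus the
# regression-based linearity diagnostics.  All bases return plain numeric
# matrices (with descriptive attributes) so they can be used directly
# inside model formulas.

new_basis <- function(m, transform, source, labels = colnames(m)) {
  attr(m, "transform") <- transform
  attr(m, "source") <- source
  attr(m, "labels") <- labels
  m
}

#' Knot locations for spline bases
#'
#' Validates an explicit, strictly increasing knot vector.  Use
#' [place_knots()] for data-driven percentile placement.
#'
#' @param knots Strictly increasing numeric vector.
#' @return The knot vector with class `knot_set`.
#' @export
knot_set <- function(knots) {
  if (!is.numeric(knots) || anyNA(knots) || is.unsorted(knots, strictly = TRUE))
    stop("`knots` must be a strictly increasing numeric vector", call. = FALSE)
  structure(as.numeric(knots), class = "knot_set")
}

#' Percentile-based knot placement
#'
#' Standard percentile placements: 3 knots at the 10th/50th/90th
#' percentiles, 4 knots at 5/35/65/95, 5 knots at 5/27.5/50/72.5/95;
#' other counts use equally spaced quantiles between the 5th and 95th
#' percentile.
#'
#' @param x Numeric data vector.
#' @param k Number of knots (>= 2).
#' @return A [knot_set()] of length `k`.
#' @export
place_knots <- function(x, k = 3) {
  if (!is.numeric(k) || length(k) != 1L || k < 2)
    stop("`k` must be an integer >= 2", call. = FALSE)
  probs <- switch(as.character(k),
                  "3" = c(0.10, 0.50, 0.90),
                  "4" = c(0.05, 0.35, 0.65, 0.95),
                  "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
                  seq(0.05, 0.95, length.out = k))
  kn <- unname(stats::quantile(x, probs, na.rm = TRUE, type = 7))
  if (any(diff(kn) <= 0))
    stop("data too discrete for ", k, " distinct percentile knots",
         call. = FALSE)
  knot_set(kn)
}

#' Dummy-variable basis from quantile categorization
#'
#' Cuts a continuous variable into `n_groups` (near-)equal-sized groups on
#' rank-based quantiles (ties broken by rank order) and returns the
#' `n_groups - 1` dummy columns with the lowest group as reference.
#'
#' @param values Numeric vector.
#' @param n_groups Number of groups (integer >= 2).
#' @return A numeric 0/1 matrix with `n_groups - 1` columns and the group
#'   index attached as attribute `"group"`.
#' @examples
#' categorize_dummies(1:8, 4)
#' @export
categorize_dummies <- function(values, n_groups) {
  if (!is.numeric(n_groups) || length(n_groups) != 1L || n_groups < 2)
    stop("`n_groups` must be an integer >= 2", call. = FALSE)
  n_groups <- as.integer(n_groups)
  if (length(unique(values)) < n_groups)
    stop("cannot form ", n_groups, " quantile groups: only ",
         length(unique(values)), " distinct values", call. = FALSE)
  r <- rank(values, ties.method = "first")
  grp <- ceiling(r * n_groups / length(values))
  m <- outer(grp, 2:n_groups, `==`) + 0
  labs <- vapply(2:n_groups, function(g) {
    v <- values[grp == g]
    sprintf("g%d[%.3g,%.3g]", g, min(v), max(v))
  }, character(1))
  colnames(m) <- paste0("cat", 2:n_groups)
  b <- new_basis(m, "dummy", deparse(substitute(values)), labs)
  attr(b, "group") <- grp
  b
}

#' Polynomial (power) terms of a variable
#'
#' Returns the columns `values^2, ..., values^degree`; the linear term is
#' supplied by the caller's design.
#'
#' @param values Numeric vector.
#' @param degree Highest power (integer >= 2).
#' @return A numeric matrix with `degree - 1` columns.
#' @export
polynomial_terms <- function(values, degree = 2) {
  if (!is.numeric(degree) || length(degree) != 1L || degree < 2)
    stop("`degree` must be an integer >= 2", call. = FALSE)
  degree <- as.integer(degree)
  m <- vapply(2:degree, function(d) values^d, numeric(length(values)))
  m <- matrix(m, nrow = length(values),
              dimnames = list(NULL, paste0("pow", 2:degree)))
  new_basis(m, "poly", deparse(substitute(values)))
}

#' Linear spline (truncated-power) basis
#'
#' Columns are the variable itself followed by one hinge term
#' `pmax(x - t, 0)` per knot, so a regression on this basis fits a
#' continuous piecewise-linear curve whose slope may change at every knot.
#'
#' @param values Numeric vector.
#' @param knots A [knot_set()] or numeric knot vector.
#' @return A numeric matrix with `1 + length(knots)` columns.
#' @export
linear_spline_basis <- function(values, knots) {
  if (!inherits(knots, "knot_set")) knots <- knot_set(knots)
  if (any(knots < min(values) | knots > max(values)))
    warning("some knots lie outside the observed data range", call. = FALSE)
  hinges <- vapply(as.numeric(knots), function(t) pmax(values - t, 0),
                   numeric(length(values)))
  m <- cbind(x = values, matrix(hinges, nrow = length(values)))
  colnames(m) <- c("x", paste0("hinge", seq_along(knots)))
  new_basis(m, "linear_spline", deparse(substitute(values)))
}

#' Restricted cubic spline basis (truncated-power form)
#'
#' With knots \eqn{t_1 < \dots < t_k} (k >= 3) the basis is the variable
#' itself plus the k - 2 restricted-cubic terms
#' \deqn{s_j(x) = \frac{(x-t_j)_+^3
#'   - (x-t_{k-1})_+^3\,\frac{t_k-t_j}{t_k-t_{k-1}}
#'   + (x-t_k)_+^3\,\frac{t_{k-1}-t_j}{t_k-t_{k-1}}}{(t_k-t_1)^2}}
#' which are constrained to be linear (here: zero curvature) below the
#' first and above the last knot.  The \eqn{(t_k-t_1)^{-2}} factor puts
#' the non-linear columns on the scale of the variable itself.
#'
#' @param values Numeric vector.
#' @param knots A [knot_set()] or numeric vector with at least 3 knots.
#' @return A numeric matrix with `1 + (k - 2)` columns.
#' @examples
#' rcs_basis(c(-1, 0.5, 1, 3), knots = c(0, 1, 2))
#' @export
rcs_basis <- function(values, knots) {
  if (!inherits(knots, "knot_set")) knots <- knot_set(knots)
  k <- length(knots)
  if (k < 3)
    stop("restricted cubic splines need at least 3 knots", call. = FALSE)
  t <- as.numeric(knots)
  denom <- (t[k] - t[1])^2
  cub <- function(u) pmax(u, 0)^3
  terms <- vapply(seq_len(k - 2), function(j) {
    (cub(values - t[j]) -
       cub(values - t[k - 1]) * (t[k] - t[j]) / (t[k] - t[k - 1]) +
       cub(values - t[k]) * (t[k - 1] - t[j]) / (t[k] - t[k - 1])) / denom
  }, numeric(length(values)))
  m <- cbind(x = values, matrix(terms, nrow = length(values)))
  colnames(m) <- c("x", paste0("rcs", seq_len(k - 2)))
  b <- new_basis(m, "rcs", deparse(substitute(values)))
  attr(b, "knots") <- t
  b
}

#' Restricted cubic spline term for model formulas
#'
#' Formula-friendly wrapper around [rcs_basis()]: `~ X + rcs(Z, 3)` expands
#' to the linear column of `Z` plus its restricted-cubic terms, with knots
#' placed at standard percentiles of the data (see [place_knots()]) when
#' `knots` is a single count.
#'
#' @param x Numeric vector (a data column, when used in a formula).
#' @param knots Either a single integer knot count (placed by
#'   [place_knots()]) or an explicit numeric knot vector.
#' @return A basis matrix suitable for use inside a model formula.
#' @export
rcs <- function(x, knots = 3) {
  if (length(knots) == 1L) knots <- place_knots(x, knots)
  rcs_basis(x, knots)
}

#' Linear spline term for model formulas
#'
#' Formula-friendly wrapper around [linear_spline_basis()]; a single
#' integer `knots` is expanded by [place_knots()].
#'
#' @inheritParams rcs
#' @return A basis matrix suitable for use inside a model formula.
#' @export
lspline <- function(x, knots = 3) {
  if (length(knots) == 1L) knots <- place_knots(x, knots)
  linear_spline_basis(x, knots)
}

#' Quantile-dummy term for model formulas
#'
#' Formula-friendly wrapper around [categorize_dummies()].
#'
#' @param x Numeric vector.
#' @param groups Number of quantile groups.
#' @return A 0/1 basis matrix suitable for use inside a model formula.
#' @export
dummy <- function(x, groups = 4) {
  categorize_dummies(x, groups)
}

#' Regression-based linearity diagnostics
#'
#' Tests whether the association between a continuous variable `a` and a
#' response `b` departs from linearity, using one of two classical
#' checks:
#'
#' * `"nonlinear_term"` — regress `b` on `a` plus its powers up to
#'   `degree` and jointly test the non-linear coefficients (F test for a
#'   continuous response, likelihood-ratio chi-square for a binary one).
#'   Under true linearity those coefficients are zero.
#' * `"categorical_trend"` — cut `a` into `n_groups` quantile groups and
#'   test the saturated category fit against a fit linear in the group
#'   index; the per-category coefficients (relative to the lowest group)
#'   are reported so a non-monotone pattern can be inspected.
#'
#' @param a Continuous explanatory vector.
#' @param b Response vector (continuous, or 0/1 when
#'   `response_kind = "binary"`).
#' @param response_kind `"continuous"` (linear model) or `"binary"`
#'   (logistic model).
#' @param method `"nonlinear_term"` or `"categorical_trend"`.
#' @param degree Highest power used by the non-linear-term method.
#' @param n_groups Number of quantile groups for the categorical method.
#' @param alpha Significance threshold for the verdict (default 0.05).
#' @return An object of class `linearity_diagnostic` with fields
#'   `method`, `statistic`, `p_value`, `verdict` and (for the categorical
#'   method) `details` holding per-category coefficients.
#' @examples
#' set.seed(1)
#' a <- rnorm(500); b <- a^2 + rnorm(500)
#' assess_linearity(a, b)
#' @export
assess_linearity <- function(a, b,
                             response_kind = c("continuous", "binary"),
                             method = c("nonlinear_term", "categorical_trend"),
                             degree = 2, n_groups = 4, alpha = 0.05) {
  response_kind <- match.arg(response_kind)
  method <- match.arg(method)
  if (length(a) != length(b))
    stop("`a` and `b` must have the same length", call. = FALSE)
  if (length(unique(b)) < 2L)
    stop("`b` is constant; no association to assess", call. = FALSE)
  if (response_kind == "binary" && !all(b %in% c(0, 1)))
    stop("binary response must be coded 0/1", call. = FALSE)

  details <- NULL
  if (method == "nonlinear_term") {
    nl <- polynomial_terms(a, degree)
    if (response_kind == "continuous") {
      full <- stats::lm(b ~ a + nl)
      red <- stats::lm(b ~ a)
      tab <- stats::anova(red, full)
      statistic <- tab$F[2]
      p_value <- tab$`Pr(>F)`[2]
    } else {
      full <- stats::glm(b ~ a + nl, family = stats::binomial())
      red <- stats::glm(b ~ a, family = stats::binomial())
      tab <- stats::anova(red, full, test = "Chisq")
      statistic <- tab$Deviance[2]
      p_value <- tab$`Pr(>Chi)`[2]
    }
    details <- stats::coef(full)[-(1:2)]
    names(details) <- colnames(nl)
  } else {
    dm <- categorize_dummies(a, n_groups)
    grp <- attr(dm, "group")
    fgrp <- factor(grp)
    if (response_kind == "continuous") {
      full <- stats::lm(b ~ fgrp)
      red <- stats::lm(b ~ grp)
      tab <- stats::anova(red, full)
      statistic <- tab$F[2]
      p_value <- tab$`Pr(>F)`[2]
    } else {
      full <- stats::glm(b ~ fgrp, family = stats::binomial())
      red <- stats::glm(b ~ grp, family = stats::binomial())
      tab <- stats::anova(red, full, test = "Chisq")
      statistic <- tab$Deviance[2]
      p_value <- tab$`Pr(>Chi)`[2]
    }
    details <- stats::coef(full)[-1]
    names(details) <- paste0("group", 2:n_groups)
  }
  structure(list(method = method, response_kind = response_kind,
                 statistic = unname(statistic), p_value = unname(p_value),
                 alpha = alpha,
                 verdict = if (p_value < alpha) "nonlinear_suspected"
                           else "linear_ok",
                 details = details),
            class = "linearity_diagnostic")
}

#' @export
print.linearity_diagnostic <- function(x, ...) {
  cat("Linearity diagnostic (", x$method, ", ",
      x$response_kind, " response)\n", sep = "")
  cat(sprintf("  statistic = %.4g, p = %.4g  ->  %s (alpha = %g)\n",
              x$statistic, x$p_value, x$verdict, x$alpha))
  if (!is.null(x$details) && length(x$details)) {
    cat("  coefficients beyond the linear term:\n")
    print(round(x$details, 4))
  }
  invisible(x)
}
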
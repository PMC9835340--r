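# Monte Carlo engine: replications, conditions, the full condition grid,
# and the absolute/relative-bias summaries.

ALL_METHODS <- c("multivariable", "ps_covariate", "ipw", "dr")

# Deterministic per-replication seed.  The stream depends only on the
# quantities that shape the generated data (master seed, n, effect size,
# replication index) so that different specification scenarios analyse
# identical datasets, and every condition is reproducible in isolation.
substream_seed <- function(master_seed, n, effect_size, rep_index) {
  key <- (as.double(master_seed) * 48271 +
            as.double(n) * 65537 +
            round(effect_size * 1000) * 2097169 +
            as.double(rep_index) * 30269) %% 2147483629
  as.integer(key)
}

#' Specify one simulation condition
#'
#' A condition is one cell of the simulation grid: a specification
#' scenario (see [scenario_spec()]), a sample size, and a single effect
#' size applied jointly to the confounder-exposure and
#' confounder-outcome coefficients (`theta1 = theta2 = gamma2 = gamma3 =
#' effect_size`), replicated `reps` times.
#'
#' @param scenario Integer 1--4.
#' @param n Sample size per replication.
#' @param effect_size Joint confounder-exposure / confounder-outcome
#'   coefficient (may be negative).
#' @param true_effect True exposure effect `gamma1` (default 0.59).
#' @param reps Number of Monte Carlo replications (default 1000).
#' @param master_seed Master seed for the substream derivation.
#' @param methods Subset of
#'   `c("multivariable", "ps_covariate", "ipw", "dr")`.
#' @param stabilized Use stabilized IPW weights? (default `TRUE`).
#' @param sigma Outcome noise standard deviation (default 1; a tiny
#'   value gives an effectively noiseless condition).
#' @param gamma2,gamma3 Optional confounder-outcome coefficients
#'   decoupled from `effect_size`; by default both equal `effect_size`
#'   (the confounder-exposure and confounder-outcome associations vary
#'   jointly).
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(scenario, n = 500, effect_size = 0.59,
                           true_effect = 0.59, reps = 1000,
                           master_seed = 1L, methods = ALL_METHODS,
                           stabilized = TRUE, sigma = 1,
                           gamma2 = NULL, gamma3 = NULL) {
  if (!scenario %in% 1:4) stop("`scenario` must be in 1:4", call. = FALSE)
  if (reps < 1) stop("`reps` must be >= 1", call. = FALSE)
  methods <- match.arg(methods, ALL_METHODS, several.ok = TRUE)
  structure(list(scenario = as.integer(scenario), n = as.integer(n),
                 effect_size = effect_size, true_effect = true_effect,
                 reps = as.integer(reps),
                 master_seed = as.integer(master_seed),
                 methods = methods, stabilized = stabilized, sigma = sigma,
                 gamma2 = if (is.null(gamma2)) effect_size else gamma2,
                 gamma3 = if (is.null(gamma3)) effect_size else gamma3),
            class = "condition_spec")
}

#' Run a single Monte Carlo replication
#'
#' Generates one dataset from the condition's data-generating parameters
#' (on the replication's deterministic substream) and applies each
#' selected estimator with the scenario's term lists.  The generated data
#' depend only on `(master_seed, n, effect_size, rep_index)`, never on
#' the scenario, so scenarios differ purely in the analysis model.
#'
#' @param spec A [condition_spec()].
#' @param rep_index Replication index (1-based).
#' @return A list with `estimates` (named numeric vector of exposure
#'   effects, `NA` on estimator failure) and `converged` (named logical).
#' @export
run_replication <- function(spec, rep_index) {
  stopifnot(inherits(spec, "condition_spec"))
  seed <- substream_seed(spec$master_seed, spec$n, spec$effect_size,
                         rep_index)
  params <- sim_params(n = spec$n,
                       theta1 = spec$effect_size, theta2 = spec$effect_size,
                       gamma1 = spec$true_effect,
                       gamma2 = spec$gamma2, gamma3 = spec$gamma3,
                       sigma = spec$sigma, seed = seed)
  dat <- generate_dataset(params)
  mspec <- scenario_spec(spec$scenario)
  est <- stats::setNames(rep(NA_real_, length(spec$methods)), spec$methods)
  conv <- stats::setNames(rep(FALSE, length(spec$methods)), spec$methods)
  for (m in spec$methods) {
    fit <- tryCatch(suppressWarnings(switch(m,
      multivariable = adjust_multivariable(dat, mspec),
      ps_covariate = adjust_ps_covariate(dat, mspec),
      ipw = adjust_ipw(dat, mspec, stabilized = spec$stabilized),
      dr = adjust_dr(dat, mspec))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      est[m] <- fit$beta1
      conv[m] <- fit$converged
    }
  }
  list(estimates = est, converged = conv)
}

#' Absolute and relative bias
#'
#' Absolute bias (AB) is the absolute difference between the mean
#' estimated exposure effect and the true effect; relative bias (RB) is
#' AB divided by the absolute true effect, so negative-effect conditions
#' also yield nonnegative RB.
#'
#' @param mean_estimate Mean estimated exposure effect over replications.
#' @param true_effect True exposure effect (nonzero).
#' @return A list with components `ab` and `rb`.
#' @examples
#' compute_bias(0.6263, 0.59)  # ab 0.0363, rb 0.0615
#' @export
compute_bias <- function(mean_estimate, true_effect) {
  if (true_effect == 0)
    stop("relative bias is undefined when `true_effect` is 0", call. = FALSE)
  ab <- abs(mean_estimate - true_effect)
  list(ab = ab, rb = ab / abs(true_effect))
}

#' Run all replications of one condition
#'
#' Runs `spec$reps` replications and aggregates per method: the mean
#' estimate over converged replications, absolute and relative bias, the
#' Monte Carlo standard error of the mean, and the converged count.
#' Non-converged replications are excluded from the mean, with their
#' count reported.
#'
#' @param spec A [condition_spec()].
#' @return An object of class `condition_result`: a data frame with one
#'   row per method and columns `method`, `mean_estimate`, `ab`, `rb`,
#'   `mc_se`, `n_converged`, plus the spec as attribute `"spec"`.
#' @export
run_condition <- function(spec) {
  stopifnot(inherits(spec, "condition_spec"))
  ests <- matrix(NA_real_, spec$reps, length(spec$methods),
                 dimnames = list(NULL, spec$methods))
  convs <- matrix(FALSE, spec$reps, length(spec$methods),
                  dimnames = list(NULL, spec$methods))
  for (r in seq_len(spec$reps)) {
    one <- run_replication(spec, r)
    ests[r, ] <- one$estimates
    convs[r, ] <- one$converged
  }
  rows <- lapply(spec$methods, function(m) {
    ok <- convs[, m] & !is.na(ests[, m])
    if (!any(ok))
      stop("no converged replications for method ", m, call. = FALSE)
    v <- ests[ok, m]
    bias <- compute_bias(mean(v), spec$true_effect)
    data.frame(method = m, mean_estimate = mean(v), ab = bias$ab,
               rb = bias$rb,
               mc_se = if (length(v) > 1) stats::sd(v) / sqrt(length(v))
                       else NA_real_,
               n_converged = sum(ok))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "spec") <- spec
  class(out) <- c("condition_result", "data.frame")
  out
}

#' @export
print.condition_result <- function(x, digits = 4, ...) {
  s <- attr(x, "spec")
  cat(sprintf("Condition: scenario %d, n = %d, effect size %g, true effect %g, %d reps\n",
              s$scenario, s$n, s$effect_size, s$true_effect, s$reps))
  print.data.frame(cbind(x[, "method", drop = FALSE],
                         round(x[, c("mean_estimate", "ab", "rb", "mc_se")],
                               digits),
                         x[, "n_converged", drop = FALSE]), row.names = FALSE)
  invisible(x)
}

#' Run a grid of simulation conditions
#'
#' Runs the Cartesian product of scenarios, sample sizes and effect
#' sizes.  The defaults reproduce the full study grid: 4 scenarios x 3
#' sample sizes x 6 effect sizes = 72 conditions at 1000 replications
#' each.  Per-condition failures are collected rather than aborting the
#' remaining conditions.
#'
#' @param scenarios Integer vector of scenarios (subset of 1:4).
#' @param sample_sizes Vector of sample sizes.
#' @param effect_sizes Vector of joint confounder-association effect
#'   sizes; the default covers negative and positive small, medium and
#'   large effects.
#' @param true_effect True exposure effect (default 0.59).
#' @param reps Replications per condition (default 1000).
#' @param master_seed Master seed; every condition derives independent
#'   substreams from it.
#' @param methods Estimators to run.
#' @param progress Print a line per finished condition?
#' @return An object of class `bias_grid`: a data frame with one row per
#'   condition x method (columns `scenario`, `n`, `effect_size`,
#'   `method`, `mean_estimate`, `ab`, `rb`, `mc_se`, `n_converged`),
#'   carrying attributes `master_seed`, `true_effect`, `failures`,
#'   `version` and `timestamp`.
#' @examples
#' \donttest{
#' g <- run_grid(scenarios = 1, sample_sizes = 500, effect_sizes = 0.59,
#'               reps = 50, master_seed = 1)
#' g
#' }
#' @export
run_grid <- function(scenarios = 1:4,
                     sample_sizes = c(200, 500, 1000),
                     effect_sizes = c(-0.59, -0.39, -0.14, 0.14, 0.39, 0.59),
                     true_effect = 0.59, reps = 1000, master_seed = 1L,
                     methods = ALL_METHODS, progress = FALSE) {
  if (!length(scenarios) || !length(sample_sizes) || !length(effect_sizes))
    stop("all grid axes must be non-empty", call. = FALSE)
  cells <- expand.grid(scenario = scenarios, n = sample_sizes,
                       effect_size = effect_sizes)
  rows <- vector("list", nrow(cells))
  failures <- list()
  for (i in seq_len(nrow(cells))) {
    sp <- condition_spec(scenario = cells$scenario[i], n = cells$n[i],
                         effect_size = cells$effect_size[i],
                         true_effect = true_effect, reps = reps,
                         master_seed = master_seed, methods = methods)
    res <- tryCatch(run_condition(sp), error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(cell = cells[i, ], message = conditionMessage(res))
      next
    }
    rows[[i]] <- cbind(cells[i, ], res, row.names = NULL)
    if (progress)
      message(sprintf("condition %d/%d done (scenario %d, n %d, effect %g)",
                      i, nrow(cells), cells$scenario[i], cells$n[i],
                      cells$effect_size[i]))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  attr(out, "master_seed") <- as.integer(master_seed)
  attr(out, "true_effect") <- true_effect
  attr(out, "failures") <- failures
  attr(out, "version") <- as.character(utils::packageVersion("confbias"))
  attr(out, "timestamp") <- format(Sys.time(), tz = "UTC")
  class(out) <- c("bias_grid", "data.frame")
  out
}

#' @export
print.bias_grid <- function(x, digits = 4, ...) {
  cat(sprintf("Simulation grid: %d condition-method rows (seed %d, true effect %g)\n",
              nrow(x), attr(x, "master_seed"), attr(x, "true_effect")))
  if (length(attr(x, "failures")))
    cat("  failed conditions:", length(attr(x, "failures")), "\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1)) &
    names(df) %in% c("mean_estimate", "ab", "rb", "mc_se")
  df[num] <- lapply(df[num], round, digits)
  print(utils::head(df, 20), row.names = FALSE)
  if (nrow(df) > 20) cat("  ...", nrow(df) - 20, "more rows\n")
  invisible(x)
}

#' @export
plot.bias_grid <- function(x, scenario = NULL, effect_size = NULL, ...) {
  df <- as.data.frame(x)
  if (!is.null(scenario)) df <- df[df$scenario %in% scenario, ]
  if (!is.null(effect_size)) df <- df[df$effect_size %in% effect_size, ]
  if (!nrow(df)) stop("no grid rows match the filter", call. = FALSE)
  methods <- unique(df$method)
  cols <- seq_along(methods)
  plot(range(df$n), range(df$ab), type = "n", log = "x",
       xlab = "sample size", ylab = "absolute bias",
       main = "Absolute bias vs sample size", ...)
  for (i in seq_along(methods)) {
    sub <- df[df$method == methods[i], ]
    sub <- stats::aggregate(ab ~ n, sub, mean)
    graphics::lines(sub$n, sub$ab, type = "b", col = cols[i], pch = 16)
  }
  graphics::legend("topright", legend = methods, col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(x)
}

#' Arrange grid results as a presentation table
#'
#' Formats one sample size and one sign of the effect axis as a wide
#' table: one row per method within scenario, and a (mean, AB, RB)
#' column triplet per effect size, every value rounded to 4 decimals.
#' Cells absent from the grid are shown as `"-"`.
#'
#' @param grid A [run_grid()] result.
#' @param n_filter Sample size to display.
#' @param sign_filter `"positive"` or `"negative"` effect sizes.
#' @return A character data frame with columns `scenario`, `method` and a
#'   `mean`/`ab`/`rb` triplet per effect size.
#' @export
assemble_table <- function(grid, n_filter = 500,
                           sign_filter = c("positive", "negative")) {
  sign_filter <- match.arg(sign_filter)
  df <- as.data.frame(grid)
  df <- df[df$n == n_filter, ]
  df <- if (sign_filter == "positive") df[df$effect_size > 0, ]
        else df[df$effect_size < 0, ]
  effects <- sort(unique(df$effect_size))
  if (sign_filter == "positive") effects <- sort(effects)  # 0.14, 0.39, 0.59
  scenarios <- sort(unique(df$scenario))
  fmt <- function(v) if (length(v)) sprintf("%.4f", v) else "-"
  rows <- list()
  for (s in scenarios) {
    for (m in intersect(ALL_METHODS, unique(df$method))) {
      row <- list(scenario = s, method = method_label(m))
      for (e in effects) {
        cell <- df[df$scenario == s & df$method == m & df$effect_size == e, ]
        tag <- sub("^-", "m", format(e))
        row[[paste0("mean_", tag)]] <- fmt(cell$mean_estimate)
        row[[paste0("ab_", tag)]] <- fmt(cell$ab)
        row[[paste0("rb_", tag)]] <- fmt(cell$rb)
      }
      rows[[length(rows) + 1L]] <- as.data.frame(row, check.names = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(scenario = integer(), method = character()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
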
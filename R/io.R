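# Tabular I/O for analysis mode and run configuration handling.  CSV is
# the single tabular dialect: comma separated, header row, "." decimal.

#' Read an analysis dataset from CSV
#'
#' Reads a delimited file, maps the named columns, drops rows with
#' missing values in any mapped column (complete-case analysis, with the
#' dropped count reported), and validates that the exposure is coded 0/1
#' and that outcome and confounders are numeric.
#'
#' @param path Path to a CSV file with a header row.
#' @param exposure,outcome Column names of the binary exposure and the
#'   continuous outcome.
#' @param confounders Character vector of confounder column names.
#' @return A data frame restricted to the mapped columns.
#' @export
read_dataset <- function(path, exposure = "X", outcome = "Y",
                         confounders = c("Z")) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path)
  cols <- c(exposure, outcome, confounders)
  missing_cols <- setdiff(cols, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  dat <- raw[, cols, drop = FALSE]
  keep <- stats::complete.cases(dat)
  if (any(!keep))
    message(sum(!keep), " row(s) with missing values in mapped columns dropped")
  dat <- dat[keep, , drop = FALSE]
  for (cc in c(outcome, confounders))
    if (!is.numeric(dat[[cc]]))
      stop("column `", cc, "` must be numeric", call. = FALSE)
  xv <- dat[[exposure]]
  if (!is.numeric(xv) || !all(xv %in% c(0, 1)))
    stop("exposure column `", exposure, "` must be coded 0/1 ",
         "(observed values: ", paste(utils::head(sort(unique(xv)), 5),
                                     collapse = ", "),
         "); recode before analysis", call. = FALSE)
  rownames(dat) <- NULL
  dat
}

#' Write a dataset to CSV
#'
#' @param data A data frame (e.g. from [generate_dataset()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(mode = "simulate",
       scenarios = 1:4,
       sample_sizes = c(200, 500, 1000),
       effect_sizes = c(-0.59, -0.39, -0.14, 0.14, 0.39, 0.59),
       true_effect = 0.59,
       reps = 1000,
       seed = 1L,
       input = NULL, exposure = NULL, outcome = NULL, confounders = NULL,
       spec = "linear",
       out_dir = ".",
       verbosity = 1L)
}

#' Load and validate a run configuration
#'
#' Reads a flat key-value configuration file (YAML syntax), fills
#' defaults (1000 replications, true effect 0.59, effect axis
#' +/-{0.14, 0.39, 0.59}, sample sizes {200, 500, 1000}), and applies
#' `overrides` last, so command-line flags win over file values.
#'
#' @param path Optional path to a configuration file.
#' @param overrides Named list of values taking precedence over the file.
#' @return A validated list of class `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::read_yaml(path)
    unknown <- setdiff(names(vals), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    cfg[names(vals)] <- vals
  }
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stop("unknown option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(overrides)] <- overrides
  if (!cfg$mode %in% c("simulate", "analyze", "diagnose"))
    stop("`mode` must be simulate, analyze or diagnose", call. = FALSE)
  if (cfg$mode %in% c("analyze", "diagnose")) {
    for (field in c("input", "exposure", "outcome", "confounders"))
      if (is.null(cfg[[field]]))
        stop(cfg$mode, " mode requires `", field, "`", call. = FALSE)
  }
  class(cfg) <- "run_config"
  cfg
}

# Small stable rolling hash of the configuration, recorded in outputs so
# any reported number can be traced to the exact settings.
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
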
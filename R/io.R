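# Validate (and lightly coerce) an observation table.  Used by every
# consumer so error messages are consistent and cite row and column.
as_observation_table <- function(df, require_n = FALSE, source = "observation table") {
  if (!is.data.frame(df)) stop(sprintf("%s must be a data frame", source), call. = FALSE)
  need <- c("act_c_h", "pct_spiked")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("%s is missing column(s): %s", source,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_num <- function(col, lo, hi) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("%s: column '%s' is not numeric (first bad value at row %d)",
                   source, col, if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    bad <- which(!is.finite(v) | v < lo | v > hi)
    if (length(bad)) {
      stop(sprintf("%s: column '%s' out of range [%g, %g] at row %d (value %g)",
                   source, col, lo, hi, bad[1], v[bad[1]]), call. = FALSE)
    }
  }
  check_num("act_c_h", 0, Inf)
  check_num("pct_spiked", 0, 100)
  if ("n_plants" %in% names(df)) {
    check_num("n_plants", 1, Inf)
  } else if (require_n) {
    stop(sprintf("%s is missing column 'n_plants'", source), call. = FALSE)
  }
  if (!"group" %in% names(df)) df$group <- "all"
  df
}

#' Read an observation table from CSV
#'
#' Expects the header `group,act_c_h,pct_spiked[,n_plants]` (extra columns
#' such as `day` or `day_act_c_h` are carried through).  Validation errors
#' name the offending row and column.
#'
#' @param path CSV file path.
#' @return A validated observation data frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop(sprintf("observation file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_observation_table(df, source = path)
}

#' Write an observation table to CSV
#'
#' Canonical column order `group,day,act_c_h,day_act_c_h,pct_spiked,n_plants`
#' (present columns only), so that write/read round-trips are
#' byte-identical for canonical files.
#'
#' @param obs Observation data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  obs <- as_observation_table(obs)
  order <- intersect(c("group", "day", "act_c_h", "day_act_c_h",
                       "pct_spiked", "n_plants"), names(obs))
  extra <- setdiff(names(obs), order)
  utils::write.csv(obs[, c(order, extra), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a sigmoid fit to JSON
#'
#' Writes parameters, fit statistics, residuals, convergence metadata and
#' a definitions block (stating the R2 and s conventions and the model
#' form) with a stable key order so fit files diff cleanly.
#'
#' @param fit A `sigmoid_fit` from [fit_sigmoid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "sigmoid_fit"))
  out <- list(
    params = if (is.null(fit$params)) NULL else fit$params[c("Ymax", "B", "K")],
    R2 = fit$R2,
    s = fit$s,
    n = fit$n,
    converged = fit$converged,
    iterations = fit$iterations,
    message = fit$message,
    residuals = fit$residuals,
    definitions = list(
      model = "Y = Ymax / (1 + B * exp(-ACT/K)); Y in percent, ACT in degC*h",
      R2 = "1 - SS_res/SS_tot with SS_tot about the mean of observed Y",
      s = "sqrt(SS_res / (n - 3)); residual standard error, 3 fitted parameters"
    )
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read sigmoid parameters from a fit JSON file
#'
#' Accepts files written by [write_fit_json()] (parameters under `params`)
#' or a bare `{"Ymax": ..., "B": ..., "K": ...}` object.
#'
#' @param path JSON file path.
#' @return A [sigmoid_params()] object.
#' @export
read_params_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- if (!is.null(x$params)) x$params else x
  if (!all(c("Ymax", "B", "K") %in% names(p))) {
    stop(sprintf("%s does not contain Ymax, B and K", path), call. = FALSE)
  }
  sigmoid_params(p$Ymax, p$B, p$K)
}
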
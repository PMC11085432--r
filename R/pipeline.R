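#' Build and validate a pipeline run configuration
#'
#' @param seed Integer seed for every stochastic stage.
#' @param out_dir Directory for artifacts (created if needed).
#' @param variety Variety preset used for scheduling (see [phal_regime()]).
#' @param target Target spiking percentage for the scheduling stage.
#' @param n_plants,days,noise Cohort settings passed to the simulator.
#' @param clamp Clamp negative differentials in the ACT index (default).
#' @param inhibition_threshold Optional high-temperature inhibition cutoff
#'   (deg C), off by default.
#' @param photoperiod Day length in hours, in (0, 24).
#' @param init Optional fit initialization override (named `Ymax`, `B`, `K`).
#' @param verbose Print stage progress.
#' @return A validated `run_config` list.
#' @export
run_config <- function(seed, out_dir = ".", variety = "KHM1220", target = 90,
                       n_plants = 1000L, days = seq(2, 40, by = 2),
                       noise = "plant_threshold", clamp = TRUE,
                       inhibition_threshold = NULL, photoperiod = 14,
                       init = NULL, verbose = TRUE) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != floor(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  if (!is.numeric(photoperiod) || photoperiod <= 0 || photoperiod >= 24) {
    stop(sprintf("'photoperiod' must be in (0, 24) hours (got %g)", photoperiod),
         call. = FALSE)
  }
  if (!is.numeric(target) || target <= 0 || target >= 100) {
    stop("'target' must be a percentage in (0, 100)", call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), out_dir = out_dir, variety = variety,
         target = target, n_plants = as.integer(n_plants), days = days,
         noise = noise, clamp = clamp,
         inhibition_threshold = inhibition_threshold,
         photoperiod = photoperiod, init = init, verbose = verbose),
    class = "run_config")
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON file with fields accepted by [run_config()]; `seed`
#'   is required.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$seed)) stop(sprintf("config %s must declare a 'seed'", path), call. = FALSE)
  allowed <- setdiff(names(formals(run_config)), "seed")
  extra <- setdiff(names(x), c("seed", allowed))
  if (length(extra)) {
    stop(sprintf("unknown config field(s) in %s: %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  do.call(run_config, x)
}

#' Run the full simulate-accumulate-fit-schedule pipeline
#'
#' End-to-end driver: generates the four-variety fixtures, writes them as
#' an observation CSV, fits the pooled sigmoid on the full ACT index,
#' writes the fit JSON, derives the cooling schedule for the configured
#' variety and target, writes the schedule JSON, and records every
#' configuration value (plus the model-form conventions) in a run log.
#' Identical config and seed give byte-identical artifacts.
#'
#' @param config A [run_config()] (or path to a JSON config file).
#' @return Invisibly, a list with the fixtures, the pooled `sigmoid_fit`,
#'   the `schedule_plan`, and the paths of all written artifacts.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  say <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    observations = file.path(config$out_dir, "observations.csv"),
    fit = file.path(config$out_dir, "fit.json"),
    schedule = file.path(config$out_dir, "schedule.json"),
    log = file.path(config$out_dir, "run_log.txt")
  )

  stage <- "simulate"
  result <- tryCatch({
    say("[simulate] generating four-variety fixtures (seed %d)", config$seed)
    fixtures <- generate_study_fixtures(
      seed = config$seed, n_plants = config$n_plants, days = config$days,
      noise = config$noise)
    varieties <- do.call(rbind, fixtures[setdiff(names(fixtures), "literature")])
    write_observations(varieties, paths$observations)

    stage <- "fit"
    say("[fit] pooled sigmoid on the full ACT index (%d rows)", nrow(varieties))
    fit <- fit_sigmoid(varieties, init = config$init)
    if (!fit$converged) {
      stop(sprintf("optimizer did not converge: %s", fit$message), call. = FALSE)
    }
    write_fit_json(fit, paths$fit)

    stage <- "schedule"
    regime <- phal_regime(config$variety)
    say("[schedule] %g %% target under regime '%s'", config$target, config$variety)
    plan <- days_to_target(fit$params, regime, config$target,
                           clamp = config$clamp,
                           inhibition_threshold = config$inhibition_threshold)
    write_schedule_json(plan, paths$schedule)

    stage <- "log"
    log_lines <- c(
      "coolact pipeline run",
      sprintf("package version: %s", as.character(utils::packageVersion("coolact"))),
      "config:",
      sprintf("  %s = %s", names(unclass(config)),
              vapply(unclass(config), function(v) {
                if (is.null(v)) "NULL" else paste(format(v), collapse = ",")
              }, character(1))),
      "model form: Y = Ymax / (1 + B * exp(-ACT/K)), Y in percent, ACT in degC*h",
      "  (reported fitted curves of this form are read as the logistic ratio,",
      "   not an additive exponential: the additive reading exceeds 100 % at ACT = 0)",
      sprintf("fitted params: Ymax = %.10g, B = %.10g, K = %.10g",
              fit$params$Ymax, fit$params$B, fit$params$K),
      sprintf("fit: R2 = %.10g, s = %.10g, n = %d, iterations = %d",
              fit$R2, fit$s, fit$n, fit$iterations),
      sprintf("schedule: %d day(s), required ACT %.6f degC*h at %g degC*h/day",
              plan$days, plan$required_act_c_h, plan$daily_increment_c_h)
    )
    writeLines(log_lines, paths$log)
    list(fixtures = fixtures, fit = fit, plan = plan, paths = paths)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  say("[done] artifacts in %s", config$out_dir)
  invisible(result)
}
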
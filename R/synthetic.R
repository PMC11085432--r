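# Run code with a temporary RNG seed, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Specify a simulated induction cohort
#'
#' A cohort spec bundles everything needed to simulate one variety's
#' induction experiment: the thermal regime, the number of plants, the
#' scoring days, the true induction curve, and the noise model.
#'
#' @param variety Cohort label.
#' @param regime A [temperature_regime()].
#' @param n_plants Number of plants in the cohort (default 1000, the
#'   commercial cohort size the defaults emulate).
#' @param days Scoring days, strictly increasing (default every 2 days to
#'   day 40).
#' @param params True [sigmoid_params()] generating the cohort (default
#'   the pooled reference curve).
#' @param noise One of:
#'   * `"plant_threshold"` (default): each plant draws a latent induction
#'     threshold `u ~ Uniform(0, 1)` once, and is scored as spiked on day
#'     `d` iff the model curve at day `d` has reached `100 * u`.  Spiking
#'     is irreversible, so counts are monotone nondecreasing over days —
#'     the statistical structure of visually scored floral-bud emergence.
#'   * `"binomial"`: independent `Binomial(n, p_d)` draws per day;
#'     non-cumulative, provided for variance calibration.
#'   * `"none"`: exact model values, no noise.
#' @param seed Integer seed; the generated table is a pure function of
#'   (spec, seed).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(variety, regime, n_plants = 1000L,
                        days = seq(2, 40, by = 2),
                        params = phal_params("pooled"),
                        noise = c("plant_threshold", "binomial", "none"),
                        seed = NULL) {
  stopifnot(is_temp_regime(regime), inherits(params, "sigmoid_params"))
  noise <- match.arg(noise)
  if (!is.numeric(n_plants) || n_plants < 1 || n_plants != floor(n_plants)) {
    stop("'n_plants' must be a positive integer", call. = FALSE)
  }
  if (length(days) < 1L || any(diff(days) <= 0) || any(days < 1)) {
    stop("'days' must be strictly increasing positive scoring days", call. = FALSE)
  }
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(
    list(variety = variety, regime = regime, n_plants = as.integer(n_plants),
         days = as.integer(days), params = params, noise = noise, seed = seed),
    class = "cohort_spec")
}

#' Simulate an induction cohort
#'
#' Generates an observation table from a [cohort_spec()]: the cumulative
#' ACT at each scoring day is computed from the regime, the true curve is
#' evaluated there, and per-plant noise is applied according to the spec's
#' noise model.  The same spec and seed always give the identical table.
#'
#' @param spec A [cohort_spec()].
#' @return An observation table: data frame with columns `group`, `day`,
#'   `act_c_h`, `day_act_c_h`, `pct_spiked`, `n_plants`.
#' @examples
#' sp <- cohort_spec("KHM1220", phal_regime("KHM1220"), seed = 1)
#' head(generate_cohort(sp))
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  series <- accumulate_regime(spec$regime, max(spec$days), index = "full")
  series_day <- accumulate_regime(spec$regime, max(spec$days), index = "day_only")
  act <- series$cumulative_c_h[spec$days]
  day_act <- series_day$cumulative_c_h[spec$days]
  p <- predict(spec$params, act) / 100   # model works in %, sim in [0,1]

  pct <- switch(spec$noise,
    none = 100 * p,
    plant_threshold = with_seed(spec$seed, {
      u <- stats::runif(spec$n_plants)
      vapply(p, function(pd) 100 * mean(u <= pd), numeric(1))
    }),
    binomial = with_seed(spec$seed, {
      100 * stats::rbinom(length(p), spec$n_plants, p) / spec$n_plants
    })
  )
  data.frame(
    group = spec$variety, day = spec$days, act_c_h = act,
    day_act_c_h = day_act, pct_spiked = pct, n_plants = spec$n_plants,
    stringsAsFactors = FALSE
  )
}

#' Generate the standard four-variety study fixtures
#'
#' Builds simulated observation tables with the structure of the
#' reference experiment: four cohorts of 1000 plants (KHM1431, KHM1220,
#' Sogo F1691, Sogo F2032) under their vegetative regimes and the shared
#' 22/19 degC, 14 h photoperiod cooling room, all governed by one common
#' true induction curve in the full ACT index; plus a "literature-like"
#' cohort generated from the previously-reported-data parameter set.
#' Because the four regimes have different daily increments (190, 110,
#' 96, 96 degC*h/day), the cohorts cover different ACT ranges at the same
#' scoring days — which is exactly what makes the day-only index
#' misalign them.
#'
#' @param seed Integer seed; fixtures are a pure function of it.
#' @param params True parameters shared by the four variety cohorts
#'   (default the pooled reference curve).
#' @param n_plants Plants per cohort (default 1000).
#' @param days Scoring days (default every 2 days to day 40).
#' @param noise Noise model for all cohorts (default `"plant_threshold"`).
#' @return A named list of five observation tables: `KHM1431`, `KHM1220`,
#'   `SogoF1691`, `SogoF2032`, `literature`.
#' @examples
#' fx <- generate_study_fixtures(seed = 1)
#' sapply(fx, nrow)
#' @export
generate_study_fixtures <- function(seed, params = phal_params("pooled"),
                                    n_plants = 1000L,
                                    days = seq(2, 40, by = 2),
                                    noise = "plant_threshold") {
  regimes <- phal_regime()
  seeds <- as.integer(seed) + seq_along(regimes)
  cohorts <- Map(function(nm, reg, s) {
    generate_cohort(cohort_spec(nm, reg, n_plants = n_plants, days = days,
                                params = params, noise = noise, seed = s))
  }, names(regimes), regimes, seeds)
  # literature-like pool: same cadence under a nominal 110 degC*h/day
  # regime, but governed by the previously-reported-data curve
  lit_spec <- cohort_spec("literature", phal_regime("KHM1220"),
                          n_plants = n_plants, days = days,
                          params = phal_params("literature"), noise = noise,
                          seed = as.integer(seed) + length(regimes) + 1L)
  cohorts$literature <- generate_cohort(lit_spec)
  cohorts
}
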
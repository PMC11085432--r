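#' ACT required to reach a target spiking percentage
#'
#' Inverts the fitted induction curve and clamps at zero: if the target is
#' already met when plants enter the cooling room (ACT = 0), no cooling is
#' required.
#'
#' @param params A [sigmoid_params()] object.
#' @param target Target inflorescence-formation percentage, in
#'   `(0, Ymax)`.  A target at or above the plateau `Ymax` is unreachable
#'   and raises an error reporting the attainable maximum.
#' @return Required ACT in deg C * h (nonnegative).
#' @examples
#' required_act(phal_params("pooled"), 90)  # about 3977 degC*h
#' @export
required_act <- function(params, target) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (!is.numeric(target) || length(target) != 1L || !is.finite(target) ||
      target <= 0) {
    stop("'target' must be a single percentage in (0, Ymax)", call. = FALSE)
  }
  if (target >= params$Ymax) {
    stop(sprintf("target %g %% is unreachable: the fitted plateau is Ymax = %g %%",
                 target, params$Ymax), call. = FALSE)
  }
  max(0, inverse_act(params, target))
}

#' Cooling days needed to reach a target spiking percentage
#'
#' Combines the fitted induction curve with a regime's daily ACT
#' increment: `days = ceiling(required_act / daily_act)`.  Whole-day
#' granularity is used because plants are moved and scored daily; the
#' final partial day is rounded up.
#'
#' @inheritParams required_act
#' @param regime A [temperature_regime()] with a positive daily ACT
#'   increment (a regime that accumulates no cooling cannot reach any
#'   target and raises an error).
#' @param clamp,inhibition_threshold Passed to [daily_act()].
#' @return An object of class `schedule_plan`: a list with `target`,
#'   `required_act_c_h`, `daily_increment_c_h`, `days`, and `trajectory`
#'   (a data frame of day, cumulative ACT and predicted percentage).
#' @examples
#' days_to_target(phal_params("pooled"), phal_regime("KHM1220"), 90)
#' @export
days_to_target <- function(params, regime, target, clamp = TRUE,
                           inhibition_threshold = NULL) {
  stopifnot(inherits(params, "sigmoid_params"), is_temp_regime(regime))
  inc <- daily_act(regime, clamp = clamp,
                   inhibition_threshold = inhibition_threshold)
  if (inc <= 0) {
    stop("regime accumulates no cooling (daily ACT increment is 0); no target is reachable",
         call. = FALSE)
  }
  req <- required_act(params, target)
  days <- if (req == 0) 0L else as.integer(ceiling(req / inc))
  traj <- if (days >= 1L) {
    d <- seq_len(days)
    data.frame(day = d, act_c_h = d * inc,
               predicted_pct = predict(params, d * inc))
  } else {
    data.frame(day = integer(0), act_c_h = numeric(0),
               predicted_pct = numeric(0))
  }
  structure(
    list(target = target, required_act_c_h = req, daily_increment_c_h = inc,
         days = days, trajectory = traj, params = params,
         regime = regime),
    class = "schedule_plan")
}

#' @export
print.schedule_plan <- function(x, ...) {
  nm <- if (is.null(x$regime$name)) "" else sprintf(" under regime '%s'", x$regime$name)
  cat(sprintf("Cooling schedule%s\n", nm))
  cat(sprintf("  target          : %g %% spiking\n", x$target))
  cat(sprintf("  required ACT    : %.4f degC*h\n", x$required_act_c_h))
  cat(sprintf("  daily increment : %g degC*h/day\n", x$daily_increment_c_h))
  cat(sprintf("  days in cooling : %d\n", x$days))
  if (x$days >= 1L) {
    cat(sprintf("  predicted %% on final day: %.2f\n",
                x$trajectory$predicted_pct[x$days]))
  }
  invisible(x)
}

#' Serialize a schedule plan to JSON
#'
#' @param plan A `schedule_plan`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(plan, path) {
  stopifnot(inherits(plan, "schedule_plan"))
  out <- list(
    target_pct = plan$target,
    required_act_c_h = plan$required_act_c_h,
    daily_increment_c_h = plan$daily_increment_c_h,
    days = plan$days,
    regime = plan$regime[c("T_vd", "T_vn", "T_cd", "T_cn", "H_d", "H_n", "name")],
    params = plan$params[c("Ymax", "B", "K")],
    trajectory = plan$trajectory
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
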
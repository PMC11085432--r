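#' Parameters of the sigmoid inflorescence-formation model
#'
#' The model relates the percentage of plants in a cohort that have formed
#' an inflorescence (spiked) to the accumulated cooling temperature ACT
#' (deg C * h):
#'
#'   `Y(ACT) = Ymax / (1 + B * exp(-ACT / K))`
#'
#' `Ymax` is the plateau percentage a variety can reach, `K` sets the ACT
#' scale over which induction proceeds, and `B` fixes the starting level
#' (`Y(0) = Ymax / (1 + B)`).  The curve reaches half its plateau at
#' `ACT = K * log(B)`.
#'
#' @param Ymax Maximum inflorescence-formation percentage, in (0, 200].
#'   Values above 100 are accepted (unconstrained fits may land there) but
#'   trigger a warning since percentages above 100 are not physical.
#' @param B Shape parameter, positive and dimensionless.
#' @param K Accumulation-temperature scale (deg C * h), positive.
#' @return An object of class `sigmoid_params`.
#' @examples
#' p <- sigmoid_params(99.31181, 83.4511, 594.1813)
#' predict(p, act = c(0, 1100, 4400))
#' @export
sigmoid_params <- function(Ymax, B, K) {
  for (v in list(Ymax = Ymax, B = B, K = K)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("Ymax, B and K must each be a single finite number", call. = FALSE)
    }
  }
  if (Ymax <= 0 || Ymax > 200) {
    stop(sprintf("Ymax = %g %% is outside (0, 200]", Ymax), call. = FALSE)
  }
  if (Ymax > 100) {
    warning(sprintf("Ymax = %g %% exceeds 100 %%; the plateau is not physical", Ymax))
  }
  if (B <= 0) stop("B must be positive", call. = FALSE)
  if (K <= 0) stop("K must be positive (degC*h)", call. = FALSE)
  structure(list(Ymax = Ymax, B = B, K = K), class = "sigmoid_params")
}

#' @export
print.sigmoid_params <- function(x, ...) {
  cat(sprintf("Sigmoid induction parameters: Ymax = %g %%, B = %g, K = %g degC*h\n",
              x$Ymax, x$B, x$K))
  cat(sprintf("  Y(0) = %.4g %%, half-plateau at ACT = %.5g degC*h\n",
              x$Ymax / (1 + x$B), x$K * log(x$B)))
  invisible(x)
}

#' Published reference parameter sets
#'
#' Fitted `(Ymax, B, K)` triplets for Phalaenopsis cool-induction reported
#' for three data groupings: `"four_variety"` (the four commercial
#' varieties KHM1431, KHM1220, Sogo F1691 and Sogo F2032 scored under a
#' 22/19 degC cooling room), `"literature"` (previously reported induction
#' data sets), and `"pooled"` (all of the above combined).
#'
#' @param model One of `"pooled"`, `"four_variety"`, `"literature"`.
#' @return A [sigmoid_params()] object.
#' @examples
#' phal_params("pooled")
#' @export
phal_params <- function(model = c("pooled", "four_variety", "literature")) {
  model <- match.arg(model)
  switch(model,
    four_variety = sigmoid_params(99.2781, 38.585, 662.397),
    literature   = sigmoid_params(98.9971, 169.87, 534.504),
    pooled       = sigmoid_params(99.31181, 83.4511, 594.1813)
  )
}

#' Predicted inflorescence-formation percentage
#'
#' Evaluates `Ymax / (1 + B * exp(-ACT/K))`.  Strictly increasing in ACT
#' and bounded in `(0, Ymax)`; negative ACT is permitted mathematically.
#'
#' @param object A [sigmoid_params()] object.
#' @param act Accumulated cooling temperature values (deg C * h).
#' @param ... Unused.
#' @return Predicted percentages, same length as `act`.
#' @export
predict.sigmoid_params <- function(object, act, ...) {
  if (!is.numeric(act) || anyNA(act) || any(!is.finite(act))) {
    stop("'act' must be finite numeric", call. = FALSE)
  }
  object$Ymax / (1 + object$B * exp(-act / object$K))
}

#' Invert the sigmoid curve: ACT needed for a target percentage
#'
#' Closed-form inversion `ACT = -K * log((Ymax/Y - 1) / B)`.  The result
#' may be negative when the target lies below the curve's value at ACT = 0.
#'
#' @param params A [sigmoid_params()] object.
#' @param y_target Target percentage, strictly inside `(0, Ymax)`.
#' @return ACT in deg C * h such that `predict(params, ACT) == y_target`.
#' @examples
#' p <- phal_params("pooled")
#' inverse_act(p, p$Ymax / 2)   # K * log(B)
#' @export
inverse_act <- function(params, y_target) {
  stopifnot(inherits(params, "sigmoid_params"))
  if (!is.numeric(y_target) || anyNA(y_target)) {
    stop("'y_target' must be numeric", call. = FALSE)
  }
  bad <- y_target <= 0 | y_target >= params$Ymax
  if (any(bad)) {
    stop(sprintf("target percentage must lie strictly inside (0, %g); got %g",
                 params$Ymax, y_target[bad][1]), call. = FALSE)
  }
  -params$K * log((params$Ymax / y_target - 1) / params$B)
}

# Model function with analytic gradient for the least-squares fitter.
sigmoid_model_fn <- function(act, Ymax, B, K) {
  e <- exp(-act / K)
  den <- 1 + B * e
  val <- Ymax / den
  grad <- cbind(
    Ymax = 1 / den,
    B = -Ymax * e / den^2,
    K = -Ymax * B * e * act / (K^2 * den^2)
  )
  attr(val, "gradient") <- grad
  val
}

default_sigmoid_init <- function(obs) {
  y <- obs$pct_spiked
  a <- obs$act_c_h
  Ymax0 <- min(100, 1.05 * max(y))
  K0 <- (max(a) - min(a)) / 4
  y_low <- max(y[a == min(a)][1], 0.5)
  B0 <- min(max(Ymax0 / y_low - 1, 1), 500)
  c(Ymax = Ymax0, B = B0, K = K0)
}

#' Fit the sigmoid induction model by nonlinear least squares
#'
#' Minimizes the unweighted sum of squared differences between observed
#' and predicted percentages using the Levenberg-Marquardt algorithm
#' (via \pkg{minpack.lm}) with an analytic Jacobian and box constraints
#' `Ymax` in (0, 200], `B > 0`, `K > 0`.  The `Ymax` bound is deliberately
#' left above 100 so that a fit attracted to the boundary is visible as
#' such rather than masquerading as convergence; a warning fires when the
#' fitted plateau exceeds 100 %.
#'
#' @param obs An observation table: data frame with columns `act_c_h`
#'   (deg C * h) and `pct_spiked` (0-100); optional `n_plants` and
#'   `group`.  At least 4 rows with non-constant ACT are required.
#' @param init Optional starting values: a [sigmoid_params()] object or
#'   named numeric `c(Ymax=, B=, K=)`.  The default start places the
#'   plateau just above the largest observed percentage, the scale at a
#'   quarter of the observed ACT span, and derives `B` from the lowest-ACT
#'   observation.
#' @param weights Optional nonnegative per-row weights (default unweighted).
#' @param max_iter Iteration cap for the optimizer.
#' @return An object of class `sigmoid_fit`: a list with elements
#'   `params` ([sigmoid_params()]), `R2`, `s` (residual standard error on
#'   `n - 3` degrees of freedom), `residuals`, `fitted`, `n`, `converged`,
#'   `iterations`, `message` and `init`.  On optimizer failure the fit is
#'   returned with `converged = FALSE` and `params = NULL` rather than
#'   raising, so callers can inspect the diagnostics.
#' @examples
#' p <- phal_params("pooled")
#' obs <- data.frame(act_c_h = seq(0, 4000, 100))
#' obs$pct_spiked <- predict(p, obs$act_c_h)
#' fit_sigmoid(obs)
#' @export
fit_sigmoid <- function(obs, init = NULL, weights = NULL, max_iter = 200L) {
  obs <- as_observation_table(obs, require_n = FALSE)
  n <- nrow(obs)
  if (n < 4L) {
    stop(sprintf("at least 4 observations are needed to fit 3 parameters (got %d)", n),
         call. = FALSE)
  }
  if (length(unique(obs$act_c_h)) < 2L) {
    stop("ACT values are all equal; the curve is not identifiable", call. = FALSE)
  }
  if (is.null(init)) {
    start <- default_sigmoid_init(obs)
  } else if (inherits(init, "sigmoid_params")) {
    start <- c(Ymax = init$Ymax, B = init$B, K = init$K)
  } else {
    if (!all(c("Ymax", "B", "K") %in% names(init))) {
      stop("'init' must have named entries Ymax, B, K", call. = FALSE)
    }
    start <- init[c("Ymax", "B", "K")]
  }
  if (!is.null(weights)) {
    if (length(weights) != n || any(weights < 0)) {
      stop("'weights' must be nonnegative, one per observation", call. = FALSE)
    }
  }

  dat <- data.frame(act = obs$act_c_h, pct = obs$pct_spiked)
  fit_args <- list(
    pct ~ sigmoid_model_fn(act, Ymax, B, K),
    data = dat, start = as.list(start),
    lower = c(Ymax = 1e-6, B = 1e-6, K = 1e-6),
    upper = c(Ymax = 200, B = Inf, K = Inf),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  if (!is.null(weights)) fit_args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, fit_args), error = function(e) e)

  # The Ymax upper bound (200) deliberately exceeds any physical plateau so
  # that boundary attraction is visible rather than hidden.  A start far from
  # the solution can still land there (a boundary-constrained local optimum);
  # restart once from the moment-based default and keep the lower-SSE fit.
  if (!inherits(fit, "error") && stats::coef(fit)[["Ymax"]] > 199) {
    fit_args$start <- as.list(default_sigmoid_init(obs))
    refit <- tryCatch(do.call(minpack.lm::nlsLM, fit_args), error = function(e) e)
    if (!inherits(refit, "error") &&
        sum(stats::resid(refit)^2) < sum(stats::resid(fit)^2)) {
      fit <- refit
    }
  }

  if (inherits(fit, "error")) {
    out <- structure(
      list(params = NULL, R2 = NA_real_, s = NA_real_,
           residuals = rep(NA_real_, n), fitted = rep(NA_real_, n),
           n = n, converged = FALSE, iterations = NA_integer_,
           message = conditionMessage(fit), init = start),
      class = "sigmoid_fit")
    return(out)
  }

  est <- stats::coef(fit)
  params <- withCallingHandlers(
    sigmoid_params(est[["Ymax"]], est[["B"]], est[["K"]]),
    warning = function(w) {
      warning(sprintf("fitted plateau Ymax = %.4g %% exceeds 100 %%", est[["Ymax"]]),
              call. = FALSE)
      invokeRestart("muffleWarning")
    })
  gof <- goodness_of_fit(obs, params)
  structure(
    list(params = params, R2 = gof$R2, s = gof$s,
         residuals = obs$pct_spiked - predict(params, obs$act_c_h),
         fitted = predict(params, obs$act_c_h),
         n = n, converged = isTRUE(fit$convInfo$isConv),
         iterations = fit$convInfo$finIter,
         message = fit$convInfo$stopMessage, init = start),
    class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, digits = 6, ...) {
  cat("Sigmoid induction model fit (unweighted least squares)\n")
  if (is.null(x$params)) {
    cat(sprintf("  FAILED: %s\n", x$message))
    return(invisible(x))
  }
  cat(sprintf("  Ymax = %.*g %%   B = %.*g   K = %.*g degC*h\n",
              digits, x$params$Ymax, digits, x$params$B, digits, x$params$K))
  r2 <- if (is.na(x$R2)) "undefined (constant response)" else sprintf("%.*g", digits, x$R2)
  cat(sprintf("  R2 = %s   s = %.*g %%   n = %d   converged: %s (%d iter)\n",
              r2, digits, x$s, x$n, x$converged, x$iterations))
  cat("  definitions: R2 = 1 - SS_res/SS_tot about the mean; s = sqrt(SS_res/(n-3))\n")
  invisible(x)
}

#' Goodness-of-fit statistics for a fitted sigmoid curve
#'
#' Computes the coefficient of determination about the mean,
#' `R2 = 1 - SS_res / SS_tot`, and the residual standard error
#' `s = sqrt(SS_res / (n - 3))` with 3 the number of model parameters.
#' When the observed percentages are constant, `SS_tot = 0` and `R2` is
#' undefined; it is reported as `NA` while `s` is still computed.
#'
#' @param obs Observation table (columns `act_c_h`, `pct_spiked`).
#' @param params A [sigmoid_params()] object.
#' @return A list with `R2`, `s`, `ss_res`, `ss_tot`, `n` and `df`.
#' @export
goodness_of_fit <- function(obs, params) {
  obs <- as_observation_table(obs, require_n = FALSE)
  stopifnot(inherits(params, "sigmoid_params"))
  n <- nrow(obs)
  if (n < 4L) stop("goodness of fit needs at least 4 observations", call. = FALSE)
  res <- obs$pct_spiked - predict(params, obs$act_c_h)
  ss_res <- sum(res^2)
  ss_tot <- sum((obs$pct_spiked - mean(obs$pct_spiked))^2)
  R2 <- if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot
  list(R2 = R2, s = sqrt(ss_res / (n - 3)), ss_res = ss_res, ss_tot = ss_tot,
       n = n, df = n - 3L)
}

#' Compare the full day+night index against the day-only index
#'
#' Fits one pooled sigmoid per accumulation index across all groups and
#' reports, per index, the pooled fit statistics and the per-group
#' residual spread about the pooled curve.  When varieties raised under
#' different vegetative regimes share one induction curve in the full ACT
#' index, dropping the night term rescales each group's abscissa by a
#' different factor, misaligning the groups; the index with the smaller
#' pooled residual standard error is flagged as preferred.
#'
#' @param obs Observation table carrying both abscissas: columns `group`,
#'   `act_c_h` (full index), `day_act_c_h` (day-only index) and
#'   `pct_spiked`.  A list of such tables is row-bound first.
#' @param ... Passed to [fit_sigmoid()].
#' @return An object of class `act_index_comparison`: a list with the two
#'   `sigmoid_fit`s, a per-index summary (`R2`, `s`), a per-group residual
#'   standard deviation table, and `preferred` (`"full"` or `"day_only"`).
#' @export
compare_indices <- function(obs, ...) {
  if (is.list(obs) && !is.data.frame(obs)) obs <- do.call(rbind, obs)
  need <- c("group", "act_c_h", "day_act_c_h", "pct_spiked")
  missing <- setdiff(need, names(obs))
  if (length(missing)) {
    stop(sprintf("index comparison needs column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  fits <- list()
  for (index in c("full", "day_only")) {
    tab <- data.frame(
      group = obs$group,
      act_c_h = if (index == "full") obs$act_c_h else obs$day_act_c_h,
      pct_spiked = obs$pct_spiked
    )
    fit <- tryCatch(fit_sigmoid(tab, ...), error = function(e) e)
    if (inherits(fit, "error") || is.null(fit$params)) {
      msg <- if (inherits(fit, "error")) conditionMessage(fit) else fit$message
      stop(sprintf("pooled fit failed for the %s index: %s", index, msg),
           call. = FALSE)
    }
    fits[[index]] <- fit
  }
  groups <- unique(obs$group)
  spread <- do.call(rbind, lapply(groups, function(g) {
    sel <- obs$group == g
    data.frame(
      group = g,
      sd_resid_full = stats::sd(fits$full$residuals[sel]),
      sd_resid_day_only = stats::sd(fits$day_only$residuals[sel])
    )
  }))
  summary <- data.frame(
    index = c("full", "day_only"),
    R2 = c(fits$full$R2, fits$day_only$R2),
    s = c(fits$full$s, fits$day_only$s)
  )
  structure(
    list(fits = fits, summary = summary, group_spread = spread,
         preferred = summary$index[which.min(summary$s)]),
    class = "act_index_comparison")
}

#' @export
print.act_index_comparison <- function(x, ...) {
  cat("Accumulation-index comparison (pooled sigmoid fits)\n")
  print(x$summary, row.names = FALSE)
  cat("Per-group residual spread about the pooled curve:\n")
  print(x$group_spread, row.names = FALSE)
  cat(sprintf("Preferred index (smaller pooled s): %s\n", x$preferred))
  invisible(x)
}
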
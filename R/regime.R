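#' Define a day/night temperature regime
#'
#' A regime describes the six-number thermal environment used by the
#' accumulated cooling temperature (ACT) index: the day and night set-points
#' of the warm vegetative stage, the day and night set-points of the cooling
#' room used for spike induction, and the photoperiod split of the 24 h cycle.
#'
#' @param T_vd Vegetative-stage day temperature (deg C).
#' @param T_vn Vegetative-stage night temperature (deg C).
#' @param T_cd Cooling-room day temperature (deg C). Default 22, the usual
#'   commercial induction set-point.
#' @param T_cn Cooling-room night temperature (deg C). Default 19.
#' @param H_d Day length (photoperiod) in hours; must be positive.
#' @param H_n Night length in hours; `H_d + H_n` must equal 24.
#' @param name Optional label for the regime (e.g. a variety name).
#'
#' @return An object of class `temp_regime`: a named list with the six
#'   set-point fields and the optional name.
#'
#' @details All temperatures must be finite and lie in the physiological
#'   window 0-45 deg C; out-of-range values are rejected at construction so
#'   downstream accumulation code never needs to re-validate.
#'
#' @examples
#' temperature_regime(27, 23)              # 27/23 vegetative, 22/19 cooling
#' temperature_regime(32, 24, name = "KHM1431")
#' @export
temperature_regime <- function(T_vd, T_vn, T_cd = 22, T_cn = 19,
                               H_d = 14, H_n = 24 - H_d, name = NULL) {
  temps <- c(T_vd = T_vd, T_vn = T_vn, T_cd = T_cd, T_cn = T_cn)
  for (nm in names(temps)) {
    v <- temps[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("regime field '%s' must be a single finite number", nm),
           call. = FALSE)
    }
    if (v < 0 || v > 45) {
      stop(sprintf("regime field '%s' = %g degC is outside the accepted window [0, 45] degC",
                   nm, v), call. = FALSE)
    }
  }
  if (!is.numeric(H_d) || length(H_d) != 1L || !is.finite(H_d) || H_d <= 0) {
    stop("H_d (day length) must be a positive number of hours", call. = FALSE)
  }
  if (!is.numeric(H_n) || length(H_n) != 1L || !is.finite(H_n) || H_n < 0) {
    stop("H_n (night length) must be a nonnegative number of hours", call. = FALSE)
  }
  if (abs(H_d + H_n - 24) > 1e-9) {
    stop(sprintf("H_d + H_n must equal 24 h (got %g + %g = %g)",
                 H_d, H_n, H_d + H_n), call. = FALSE)
  }
  structure(
    list(T_vd = T_vd, T_vn = T_vn, T_cd = T_cd, T_cn = T_cn,
         H_d = H_d, H_n = H_n, name = name),
    class = "temp_regime"
  )
}

#' @export
print.temp_regime <- function(x, ...) {
  nm <- if (is.null(x$name)) "" else paste0(" '", x$name, "'")
  cat(sprintf("Temperature regime%s\n", nm))
  cat(sprintf("  vegetative : %g / %g degC (day/night)\n", x$T_vd, x$T_vn))
  cat(sprintf("  cooling    : %g / %g degC (day/night)\n", x$T_cd, x$T_cn))
  cat(sprintf("  photoperiod: %g h day / %g h night\n", x$H_d, x$H_n))
  invisible(x)
}

is_temp_regime <- function(x) inherits(x, "temp_regime")

#' Reference regimes for the four commercial Phalaenopsis varieties
#'
#' Vegetative set-points for the varieties KHM1431 (32/24 degC), KHM1220
#' (27/23 degC), Sogo F1691 and Sogo F2032 (both 26/23 degC), each paired
#' with the standard 22/19 degC cooling room under a 14 h photoperiod.
#'
#' @param name Optional variety name; if supplied, the single matching
#'   regime is returned, otherwise a named list of all four.
#' @return A `temp_regime`, or a named list of them.
#' @examples
#' phal_regime("KHM1220")
#' names(phal_regime())
#' @export
phal_regime <- function(name = NULL) {
  presets <- list(
    KHM1431  = temperature_regime(32, 24, name = "KHM1431"),
    KHM1220  = temperature_regime(27, 23, name = "KHM1220"),
    SogoF1691 = temperature_regime(26, 23, name = "SogoF1691"),
    SogoF2032 = temperature_regime(26, 23, name = "SogoF2032")
  )
  if (is.null(name)) return(presets)
  if (!name %in% names(presets)) {
    stop(sprintf("unknown variety '%s'; available: %s",
                 name, paste(names(presets), collapse = ", ")), call. = FALSE)
  }
  presets[[name]]
}

#' Read temperature regimes from CSV
#'
#' Expects the header `name,T_vd,T_vn,T_cd,T_cn,H_d,H_n`, one regime per row.
#'
#' @param path CSV file path.
#' @param name Optional regime name; if supplied only that row is returned
#'   as a single `temp_regime`, otherwise a named list of regimes.
#' @return A `temp_regime` or named list of them.
#' @export
read_regimes <- function(path, name = NULL) {
  if (!file.exists(path)) stop(sprintf("regime file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "T_vd", "T_vn", "T_cd", "T_cn", "H_d", "H_n")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop(sprintf("regime file %s is missing column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  regs <- lapply(seq_len(nrow(df)), function(i) {
    temperature_regime(df$T_vd[i], df$T_vn[i], df$T_cd[i], df$T_cn[i],
                       df$H_d[i], df$H_n[i], name = df$name[i])
  })
  names(regs) <- df$name
  if (is.null(name)) return(regs)
  if (!name %in% names(regs)) {
    stop(sprintf("no regime named '%s' in %s", name, path), call. = FALSE)
  }
  regs[[name]]
}

#' Write temperature regimes to CSV
#'
#' @param regimes A `temp_regime` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_regimes <- function(regimes, path) {
  if (is_temp_regime(regimes)) regimes <- list(regimes)
  df <- do.call(rbind, lapply(regimes, function(r) {
    data.frame(name = if (is.null(r$name)) NA_character_ else r$name,
               T_vd = r$T_vd, T_vn = r$T_vn, T_cd = r$T_cd, T_cn = r$T_cn,
               H_d = r$H_d, H_n = r$H_n)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
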
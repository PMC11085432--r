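# Noise-free observation table on an ACT grid.
noise_free_obs <- function(params, acts = seq(0, 4000, by = 100)) {
  data.frame(act_c_h = acts, pct_spiked = predict(params, acts))
}

# Square-wave hourly temperature log emulating a constant set-point
# regime: `temp_day` during [lights_on, lights_on + h_d), `temp_night`
# otherwise, sampled on the hour for `n_days` calendar days.
square_wave_log <- function(temp_day, temp_night, n_days = 3,
                            lights_on = 8, h_d = 14) {
  t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")
  ts <- t0 + 3600 * seq_len(24 * n_days) - 3600
  hour <- as.numeric(format(ts, "%H"))
  temp <- ifelse(hour >= lights_on & hour < lights_on + h_d,
                 temp_day, temp_night)
  temperature_log(ts, temp)
}

# Random valid regime (used by property loops).
random_regime <- function() {
  T_cd <- runif(1, 15, 25)
  T_cn <- runif(1, 12, 22)
  temperature_regime(
    T_vd = runif(1, 18, 35), T_vn = runif(1, 15, 30),
    T_cd = T_cd, T_cn = T_cn,
    H_d = sample(8:16, 1)
  )
}

# Random valid sigmoid parameter set (used by property loops).
random_params <- function() {
  sigmoid_params(Ymax = runif(1, 40, 100), B = runif(1, 2, 300),
                 K = runif(1, 200, 1500))
}
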
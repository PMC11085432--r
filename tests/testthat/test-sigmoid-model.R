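pooled <- phal_params("pooled")

test_that("parameter construction enforces the physical ranges", {
  expect_error(sigmoid_params(0, 10, 300), "Ymax")
  expect_error(sigmoid_params(50, -1, 300), "B")
  expect_error(sigmoid_params(50, 10, 0), "K")
  expect_warning(sigmoid_params(150, 10, 300), "100")
})

test_that("the forward curve evaluates, saturates and has its analytic midpoint", {
  expect_equal(predict(pooled, 0), 1.175968, tolerance = 1e-6)
  expect_equal(predict(pooled, 1e7), pooled$Ymax, tolerance = 1e-10)
  expect_equal(predict(pooled, pooled$K * log(pooled$B)), pooled$Ymax / 2,
               tolerance = 1e-12)
  set.seed(21)
  for (i in 1:20) {
    p <- random_params()
    acts <- sort(runif(50, -500, 8000))
    y <- predict(p, acts)
    expect_true(all(diff(y) > 0))          # strictly increasing
    expect_true(all(y > 0 & y < p$Ymax))   # open bounds
  }
})

test_that("closed-form inversion round-trips and matches a bisection oracle", {
  expect_equal(inverse_act(pooled, pooled$Ymax / 2), 2628.8131, tolerance = 1e-4)
  for (act in c(0, 500, 2000)) {
    expect_equal(inverse_act(pooled, predict(pooled, act)), act, tolerance = 1e-9)
  }
  set.seed(33)
  for (i in 1:20) {
    p <- random_params()
    y <- runif(1, 0.02, 0.98) * p$Ymax
    a <- inverse_act(p, y)
    expect_equal(predict(p, a), y, tolerance = 1e-9)
    # independent bisection on the forward curve
    lo <- -1e5; hi <- 1e6
    for (j in 1:80) {
      mid <- (lo + hi) / 2
      if (predict(p, mid) < y) lo <- mid else hi <- mid
    }
    expect_equal(a, (lo + hi) / 2, tolerance = 1e-5)
  }
  expect_error(inverse_act(pooled, 100), "inside")
  expect_error(inverse_act(pooled, 0), "inside")
})

test_that("noise-free data return the generating parameters", {
  for (truth in list(pooled, sigmoid_params(50, 10, 300))) {
    fit <- fit_sigmoid(noise_free_obs(truth))
    expect_true(fit$converged)
    expect_equal(fit$params$Ymax, truth$Ymax, tolerance = 1e-4)
    expect_equal(fit$params$B, truth$B, tolerance = 1e-4)
    expect_equal(fit$params$K, truth$K, tolerance = 1e-4)
    expect_equal(fit$R2, 1, tolerance = 1e-10)
    expect_lt(fit$s, 1e-6)
  }
})

test_that("recovery succeeds from across the documented initialization basin", {
  obs <- noise_free_obs(pooled)
  set.seed(5)
  for (i in 1:10) {
    init <- c(Ymax = runif(1, 80, 120), B = runif(1, 1, 500),
              K = runif(1, 100, 2000))
    fit <- fit_sigmoid(obs, init = init)
    expect_true(fit$converged)
    expect_equal(fit$params$K, pooled$K, tolerance = 1e-4)
  }
})

test_that("the fit agrees with an independent optimizer", {
  obs <- noise_free_obs(sigmoid_params(80, 40, 700), acts = seq(0, 5000, 250))
  ours <- fit_sigmoid(obs)
  ref <- stats::nls(pct_spiked ~ Ymax / (1 + B * exp(-act_c_h / K)),
                    data = obs, start = list(Ymax = 100, B = 10, K = 500),
                    algorithm = "port", lower = c(1e-6, 1e-6, 1e-6))
  expect_equal(ours$params$Ymax, coef(ref)[["Ymax"]], tolerance = 1e-5)
  expect_equal(ours$params$B, coef(ref)[["B"]], tolerance = 1e-5)
  expect_equal(ours$params$K, coef(ref)[["K"]], tolerance = 1e-5)
})

test_that("degenerate fitting inputs are rejected or flagged, never silent", {
  expect_error(fit_sigmoid(noise_free_obs(pooled, acts = c(0, 100, 200))),
               "at least 4")
  same_act <- data.frame(act_c_h = rep(100, 5), pct_spiked = 1:5 * 10)
  expect_error(fit_sigmoid(same_act), "identifiable")
  bad_init <- fit_sigmoid(noise_free_obs(pooled),
                          init = c(Ymax = NA_real_, B = 1, K = 1))
  expect_false(bad_init$converged)
  expect_null(bad_init$params)
  expect_type(bad_init$message, "character")
})

test_that("fit statistics match a brute-force sum-of-squares recomputation", {
  set.seed(44)
  for (i in 1:20) {
    p <- random_params()
    acts <- runif(10, 0, 6000)
    obs <- data.frame(act_c_h = acts,
                      pct_spiked = pmin(100, pmax(0, predict(p, acts) + rnorm(10, 0, 5))))
    gof <- goodness_of_fit(obs, p)
    res <- obs$pct_spiked - p$Ymax / (1 + p$B * exp(-obs$act_c_h / p$K))
    ss_res <- sum(res^2)
    ss_tot <- sum((obs$pct_spiked - mean(obs$pct_spiked))^2)
    expect_equal(gof$R2, 1 - ss_res / ss_tot, tolerance = 1e-12)
    expect_equal(gof$s, sqrt(ss_res / (nrow(obs) - 3)), tolerance = 1e-12)
  }
})

test_that("hand-computed residual table gives the expected R2 and s", {
  p <- sigmoid_params(90, 20, 500)
  acts <- c(0, 500, 1000, 1500, 2000)
  resid <- c(1, -1, 2, -2, 0)                      # SS_res = 10
  obs <- data.frame(act_c_h = acts,
                    pct_spiked = predict(p, acts) + resid)
  gof <- goodness_of_fit(obs, p)
  ss_tot <- sum((obs$pct_spiked - mean(obs$pct_spiked))^2)
  expect_equal(gof$ss_res, 10, tolerance = 1e-10)
  expect_equal(gof$R2, 1 - 10 / ss_tot, tolerance = 1e-12)
  expect_equal(gof$s, sqrt(10 / 2), tolerance = 1e-12)  # df = 5 - 3
})

test_that("zero residuals give perfect statistics; constant response leaves R2 undefined", {
  obs <- noise_free_obs(pooled, acts = seq(500, 2000, 500))
  gof <- goodness_of_fit(obs, pooled)
  expect_equal(gof$R2, 1)
  expect_equal(gof$s, 0)
  const <- data.frame(act_c_h = c(0, 1000, 2000, 3000), pct_spiked = rep(50, 4))
  gof2 <- goodness_of_fit(const, pooled)
  expect_true(is.na(gof2$R2))
  expect_gte(gof2$s, 0)
})

test_that("the full day+night index pools varieties better than day-only", {
  fx <- generate_study_fixtures(seed = 7)
  varieties <- do.call(rbind, fx[c("KHM1431", "KHM1220", "SogoF1691", "SogoF2032")])
  cmp <- compare_indices(varieties)
  expect_lt(cmp$summary$s[cmp$summary$index == "full"],
            cmp$summary$s[cmp$summary$index == "day_only"])
  expect_identical(cmp$preferred, "full")
  expect_equal(nrow(cmp$group_spread), 4)
})

test_that("a single group still yields a defined (degenerate) comparison", {
  fx <- generate_study_fixtures(seed = 9)
  cmp <- compare_indices(fx$KHM1220)
  expect_equal(nrow(cmp$group_spread), 1)
  expect_true(all(is.finite(cmp$summary$s)))
})

test_that("proportional abscissas give identical pooled fit quality", {
  # all groups under one regime: Day-ACT is a constant multiple of ACT,
  # so the sigmoid family absorbs the rescaling into K
  spec1 <- cohort_spec("a", phal_regime("KHM1220"), noise = "none")
  spec2 <- cohort_spec("b", phal_regime("KHM1220"), noise = "none")
  obs <- rbind(generate_cohort(spec1), generate_cohort(spec2))
  cmp <- compare_indices(obs)
  expect_equal(cmp$summary$R2[1], cmp$summary$R2[2], tolerance = 1e-6)
  expect_equal(cmp$fits$day_only$params$K * (110 / 70),
               cmp$fits$full$params$K, tolerance = 1e-3)
})
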
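test_that("detrending removes ramps and keeps full-period cosines", {
  t <- seq(0, 120, by = 0.5)
  ramp <- 5 + 2 * t
  d <- detrend(ramp, t)
  inner <- t > 12 & t < 108
  expect_true(all(abs(d[inner]) < 1e-9))

  cosy <- 300 * cos(2 * pi * t / 24)
  dc <- detrend(cosy, t)
  expect_equal(dc[inner], cosy[inner], tolerance = 1e-6)

  # a second pass only sees edge distortion propagating one window inward,
  # so idempotence holds on the deeper interior
  dd <- detrend(dc, t)
  deep <- t > 24 & t < 96
  expect_equal(dd[deep], dc[deep], tolerance = 1e-6)
  expect_error(detrend(1:10, seq(0, 4.5, 0.5)), "window")
})

test_that("noiseless damped cosines are recovered to high precision", {
  tr <- simulate_reporter(period_h = 24.5, amplitude = 800,
                          damping_rate = 0.01, noise_sd = 0)
  fit <- fit_damped_cosine(tr$counts, tr$time_h)
  expect_lt(abs(fit$period - 24.5), 0.05)
  expect_gt(fit$r, 0.999)
  expect_true(fit$rhythmic)
  expect_lt(abs(fit$damping - 0.01), 0.002)
  expect_lt(abs(fit$amplitude - 800) / 800, 0.02)
})

test_that("white-noise traces are classified arrhythmic", {
  set.seed(1)
  t <- seq(0, 144, by = 0.5)
  for (i in 1:5) {
    fit <- fit_damped_cosine(rnorm(length(t), 0, 100), t)
    expect_lt(fit$r, 0.8)
    expect_false(fit$rhythmic)
  }
})

test_that("fits are canonical (A > 0, phase in [0, period)) and scale-free r", {
  tr <- simulate_reporter(period_h = 22, amplitude = 400, damping_rate = 0.02,
                          noise_sd = 40, seed = 2)
  fit <- fit_damped_cosine(tr$counts, tr$time_h)
  expect_gt(fit$amplitude, 0)
  expect_gte(fit$phase, 0)
  expect_lt(fit$phase, fit$period)
  fit2 <- fit_damped_cosine(tr$counts * 7.3, tr$time_h)
  expect_equal(fit$r, fit2$r, tolerance = 1e-6)
})

test_that("fit methods: coef, predict, fitted, residuals, simulate", {
  tr <- simulate_reporter(period_h = 25, noise_sd = 30, seed = 3)
  fit <- fit_damped_cosine(tr$counts, tr$time_h)
  expect_named(coef(fit), c("period", "amplitude", "damping", "phase", "r"))
  expect_equal(length(fitted(fit)), nrow(tr))
  expect_equal(fitted(fit) + residuals(fit), tr$counts, tolerance = 1e-9)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-6)
  sims <- simulate(fit, nsim = 2, seed = 4)
  expect_length(sims, 2)
  expect_output(print(fit), "period")
})

test_that("parameter recovery: median period error < 0.1 h at SNR 10", {
  set.seed(5)
  errs <- vapply(1:30, function(i) {
    tau <- runif(1, 22, 26)
    tr <- simulate_reporter(period_h = tau, amplitude = 500,
                            damping_rate = 0.015, noise_sd = 50,
                            seed = 1000 + i)
    fit <- fit_damped_cosine(tr$counts, tr$time_h)
    abs(fit$period - tau)
  }, numeric(1))
  expect_lt(stats::median(errs), 0.1)
})

test_that("period deviations follow the control-mean arithmetic", {
  expect_equal(period_deviation(25.1, c(24.0, 24.2))$delta, 1.0,
               tolerance = 1e-12)
  expect_equal(period_deviation(24.1, c(24.0, 24.2))$delta, 0.0,
               tolerance = 1e-12)
  both <- period_deviation(c(25.0, 25.4), c(24, 24.2))
  expect_equal(both$delta, 1.1, tolerance = 1e-12)
  expect_equal(both$sem, stats::sd(c(25, 25.4)) / sqrt(2))
  expect_error(period_deviation(25, 24), "controls")
})

test_that("arrhythmic samples propagate the flag with no deviation", {
  tr <- simulate_reporter(noise_sd = 0)
  good <- fit_damped_cosine(tr$counts, tr$time_h)
  set.seed(6)
  bad <- fit_damped_cosine(rnorm(289, 0, 50), tr$time_h)
  out <- period_deviation(bad, list(good, good))
  expect_true(out$arrhythmic)
  expect_true(is.na(out$delta))
})

test_that("phenotypic score follows the rule table", {
  expect_equal(phenotypic_score(kd = data.frame(delta = 0.1),
                                oe = data.frame(delta = 0.2)), 0)
  expect_equal(phenotypic_score(kd = data.frame(delta = NA, arrhythmic = TRUE),
                                oe = data.frame(delta = 2.5)), 5)
  expect_equal(phenotypic_score(kd = data.frame(delta = 1)), 1)
  expect_equal(phenotypic_score(kd = data.frame(delta = -0.7)), 1)
  expect_equal(phenotypic_score(kd = data.frame(delta = 0.1,
                                                amp_flag = TRUE)), 1)
  expect_equal(phenotypic_score(kd = data.frame(delta = -3),
                                oe = data.frame(delta = NA,
                                                arrhythmic = TRUE)), 5)
  expect_error(phenotypic_score(), "no perturbation")
})

test_that("replicate agreement: the direction score is the reproduced one", {
  two <- data.frame(delta = c(2.5, 2.6))
  expect_equal(phenotypic_score(kd = two), 2)
  mixed <- data.frame(delta = c(0.1, 2.6))
  expect_equal(phenotypic_score(kd = mixed), 0)
})

test_that("phenotypic score is monotone under worsening inputs", {
  set.seed(7)
  for (i in 1:50) {
    kd <- data.frame(delta = runif(2, 0, 3),
                     arrhythmic = FALSE,
                     amp_flag = runif(2) < 0.3, damp_flag = runif(2) < 0.3)
    oe <- data.frame(delta = runif(1, 0, 3), arrhythmic = runif(1) < 0.2)
    oe$delta[oe$arrhythmic] <- NA
    base <- phenotypic_score(kd, oe)
    worse <- kd
    j <- sample(2, 1)
    worse$delta[j] <- worse$delta[j] + runif(1, 0, 3)
    expect_gte(phenotypic_score(worse, oe), base)
    flagged <- kd; flagged$amp_flag <- TRUE
    expect_gte(phenotypic_score(flagged, oe), base)
  }
})

test_that("scores separate by dynamic degree when planted, not under the null", {
  set.seed(8)
  dd <- stats::setNames(c(rpois(40, 10) + 5, rpois(40, 1)), paste0("p", 1:80))
  planted <- stats::setNames(ifelse(dd >= 5, rpois(80, 3), rpois(80, 0.5)),
                             names(dd))
  hot <- score_vs_dynamic_degree(planted, dd, cut = 5)
  expect_lt(hot$t_test$p.value, 0.01)
  expect_lt(hot$mann_whitney$p.value, 0.01)
  expect_gt(hot$mean_high, hot$mean_low)

  null_scores <- stats::setNames(rpois(80, 2), names(dd))
  nul <- score_vs_dynamic_degree(null_scores, dd, cut = 5)
  expect_gt(nul$mann_whitney$p.value, 0.01)
  expect_error(score_vs_dynamic_degree(planted, dd, cut = 1000), "empty")
})
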
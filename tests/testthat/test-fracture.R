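test_that("rate_to_probability matches its closed form and stays below r*t", {
  expect_identical(rate_to_probability(0, 1), 0)
  expect_equal(rate_to_probability(0.01, 1), 0.00995, tolerance = 5e-4)
  expect_equal(rate_to_probability(2, 1), 0.8647, tolerance = 5e-5)
  expect_error(rate_to_probability(-0.1), class = "osteo_domain_error")
  expect_error(rate_to_probability(0.1, 0), class = "osteo_domain_error")

  rates <- c(1e-5, 1e-3, 0.05, 0.5, 3)
  ts <- c(0.25, 1, 2)
  for (tt in ts) {
    p <- rate_to_probability(rates, tt)
    expect_true(all(p <= rates * tt))
    expect_true(all(p >= 0 & p < 1))
  }
  # first-order agreement within 1% when r*t < 0.01
  small <- c(1e-6, 1e-4, 5e-3)
  expect_true(all(abs(rate_to_probability(small, 1) - small) / small < 0.01))
  # monotone in both arguments
  expect_true(all(diff(rate_to_probability(rates, 1)) > 0))
  expect_true(all(diff(rate_to_probability(0.1, ts)) > 0))
})

test_that("BMD trajectories lose T-score on AI therapy and by age table off it", {
  p <- default_params()
  b <- list(tscore = -1.0, age = 62)
  on <- update_bmd(b, on_ai = TRUE, p)
  expect_equal(on$tscore, -1.0 - p$bmd_loss_on_ai)
  expect_equal(on$tscore, -1.12)
  expect_identical(on$age, 63)

  off <- update_bmd(list(tscore = -1.0, age = 72), on_ai = FALSE, p)
  nat <- p$bmd_loss_natural$loss[p$bmd_loss_natural$age == 70]
  expect_equal(off$tscore, -1.0 - nat)

  p0 <- with_param(p, "bmd_loss_on_ai", 0)
  expect_equal(update_bmd(b, TRUE, p0)$tscore, b$tscore)
})

test_that("T-score/Z-score conversion is the identity at the young-adult age and inverts exactly", {
  p <- default_params()
  ya <- p$young_adult_age
  for (t in c(-3, -1.2, 0.5)) {
    expect_equal(tscore_to_zscore(t, ya, p), t)
  }
  # age 70 fixture: population mean T -1.7, SD 1
  expect_equal(tscore_to_zscore(-2.5, 70, p), (-2.5 - (-1.7)) / 1)
  for (age in c(60, 72, 85)) {
    z <- tscore_to_zscore(-2.1, age, p)
    expect_equal(zscore_to_tscore(z, age, p), -2.1, tolerance = 1e-9)
  }
  expect_error(tscore_to_zscore(-1, 20, p), class = "osteo_range_error")
})

test_that("fracture rates follow the age curve, BMD gradient and repeat-fracture rule", {
  p <- default_params()
  # at the age-matched mean BMD (Z = 0) the rate is the bare curve value
  t70 <- zscore_to_tscore(0, 70, p)
  fr <- fracture_rate("hip", list(tscore = t70, age = 70), FALSE, p)
  curve <- unlist(p$fracture_rate_curves$hip)
  expect_equal(fr$annual_rate, curve[["a"]] * exp(curve[["b"]] * 70))
  expect_equal(fr$cycle_probability, rate_to_probability(fr$annual_rate))

  # one SD below the age-matched mean multiplies by the gradient
  t_low <- zscore_to_tscore(-1, 70, p)
  fr_low <- fracture_rate("hip", list(tscore = t_low, age = 70), FALSE, p)
  expect_equal(fr_low$annual_rate,
               fr$annual_rate * p$gradient_rr_per_sd$hip)

  # prior fracture multiplies non-vertebral sites, never vertebral
  fr_sub <- fracture_rate("hip", list(tscore = t70, age = 70), TRUE, p)
  expect_equal(fr_sub$annual_rate,
               fr$annual_rate * p$rr_subsequent_fracture$hip)
  v0 <- fracture_rate("vertebral", list(tscore = t70, age = 70), FALSE, p)
  v1 <- fracture_rate("vertebral", list(tscore = t70, age = 70), TRUE, p)
  expect_identical(v1$annual_rate, v0$annual_rate)
})

test_that("fracture risk is monotone in T-score and age over the fixture curves", {
  p <- default_params()
  ts <- seq(-4, 2, by = 0.5)
  for (site in c("hip", "vertebral", "other")) {
    r <- vapply(ts, function(t) {
      fracture_rate(site, list(tscore = t, age = 70), FALSE, p)$annual_rate
    }, numeric(1))
    expect_true(all(diff(r) < 0))
    r_age <- vapply(c(60, 65, 70, 80, 90), function(a) {
      t <- zscore_to_tscore(-0.5, a, p)
      fracture_rate(site, list(tscore = t, age = a), FALSE, p)$annual_rate
    }, numeric(1))
    expect_true(all(diff(r_age) > 0))
  }
})

test_that("treatment effect holds on therapy and decays linearly to exactly 1", {
  p <- default_params()
  expect_equal(treatment_rr("alendronate", "hip", -1, p), 0.60)
  expect_equal(treatment_rr("alendronate", "hip", 0, p), 0.60) # continuity
  expect_equal(treatment_rr("alendronate", "hip", 2.5, p), 0.80)
  expect_identical(treatment_rr("alendronate", "hip", 5, p), 1)
  expect_identical(treatment_rr("alendronate", "hip", 12, p), 1)
  # no residual effect configured for denosumab
  expect_equal(treatment_rr("denosumab", "vertebral", -1, p), 0.32)
  expect_identical(treatment_rr("denosumab", "vertebral", 0.01, p), 1)
  expect_error(treatment_rr("estrogen", "hip", 0, p),
               class = "osteo_config_error")
  # always within [configured RR, 1] and non-decreasing after stop
  tt <- seq(0, 8, by = 0.1)
  rr <- treatment_rr("alendronate", "other", tt, p)
  expect_true(all(rr >= 0.80 - 1e-12 & rr <= 1 + 1e-12))
  expect_true(all(diff(rr) >= 0))
})
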
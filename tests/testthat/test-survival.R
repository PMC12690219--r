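km_of <- function(ipd, times) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  summary(sf, times = times, extend = TRUE)$surv
}

test_that("km_curve enforces its invariants", {
  expect_error(km_curve(c(0, 1), c(1, 0.5),
                        data.frame(time = c(0, 1), n_risk = c(5, 10))),
               class = "osteo_km_error")
  expect_error(km_curve(c(0, 1), c(0.5, 1),
                        data.frame(time = c(0, 1), n_risk = c(10, 5))),
               "non-increasing")
  expect_error(km_curve(c(-1, 1), c(1, 0.5),
                        data.frame(time = c(0, 1), n_risk = c(10, 5))),
               "non-negative")
})

test_that("digitized curves round-trip through delimited text files", {
  mk <- make_km("exponential", c(rate = 0.2), n = 200, censor_time = 4,
                seed = 2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = mk$km$times,
                              survival = mk$km$survival),
                   f1, row.names = FALSE)
  utils::write.csv(mk$km$risk_table, f2, row.names = FALSE)
  km <- read_km(f1, f2, total_events = mk$km$total_events)
  expect_equal(km$times, mk$km$times)
  expect_equal(km$survival, mk$km$survival)
  expect_equal(km$risk_table$n_risk, mk$km$risk_table$n_risk)
})

test_that("reconstructed pseudo-IPD reproduces the digitized KM curve", {
  mk <- make_km("exponential", c(rate = 0.1), n = 500, censor_time = 5,
                seed = 7)
  ipd <- reconstruct_ipd(mk$km)
  expect_equal(nrow(ipd), 500)
  dev <- abs(km_of(ipd, mk$km$times) - mk$km$survival)
  expect_lt(max(dev), 0.02)
})

test_that("a flat survival curve reconstructs to censored-only records", {
  km <- km_curve(times = 0:5, survival = rep(1, 6),
                 risk_table = data.frame(time = 0:5, n_risk = rep(50, 6)))
  ipd <- reconstruct_ipd(km)
  expect_identical(sum(ipd$event), 0L)
  expect_equal(nrow(ipd), 50)
})

test_that("a two-point curve halving survival yields the exact event count", {
  km <- km_curve(times = c(0, 1), survival = c(1, 0.5),
                 risk_table = data.frame(time = c(0, 1), n_risk = c(10, 5)))
  ipd <- reconstruct_ipd(km)
  expect_identical(sum(ipd$event), 5L)
  expect_true(all(ipd$time[ipd$event == 1] <= 1))
})

test_that("maximum-likelihood fitting recovers log-normal parameters and AIC orders models", {
  mk <- make_km("lognormal", c(meanlog = 1.0, sdlog = 0.5), n = 2000,
                censor_time = Inf, seed = 3)
  f <- fit_parametric(mk$ipd, "lognormal")
  expect_lt(abs(f$params[["meanlog"]] - 1.0), 0.05)
  expect_lt(abs(f$params[["sdlog"]] - 0.5), 0.05)
  f_exp <- fit_parametric(mk$ipd, "exponential")
  expect_lt(f$aic, f_exp$aic)
})

test_that("degenerate fitting inputs raise typed errors", {
  all_cens <- tibble::tibble(time = seq_len(20), event = rep(0L, 20))
  expect_error(fit_parametric(all_cens, "weibull"),
               class = "osteo_fit_error")
  tiny <- tibble::tibble(time = 1:5, event = rep(1L, 5))
  expect_error(fit_parametric(tiny, "weibull"), class = "osteo_fit_error")
})

test_that("select_best minimises AIC with documented tie-breaks", {
  f1 <- survival_fit("weibull", c(shape = 1, scale = 2), aic = 100)
  f2 <- survival_fit("lognormal", c(meanlog = 0, sdlog = 1), aic = 98)
  expect_identical(select_best(list(f1, f2))$distribution, "lognormal")
  # equal AIC: exponential (1 parameter) beats weibull (2)
  f3 <- survival_fit("exponential", c(rate = 0.5), aic = 100)
  expect_identical(select_best(list(f1, f3))$distribution, "exponential")
  expect_identical(select_best(list(f1))$distribution, "weibull")
  expect_error(select_best(list()), class = "osteo_fit_error")
})

test_that("survival_at evaluates the documented closed forms", {
  ln <- survival_fit("lognormal", c(meanlog = 0, sdlog = 1))
  expect_equal(survival_at(ln, 1), 0.5)
  expect_equal(survival_at(ln, 0), 1)
  ln2 <- survival_fit("lognormal", c(meanlog = 1, sdlog = 0.5))
  expect_equal(survival_at(ln2, exp(1)), 0.5)
  expect_error(survival_at(ln, -1), class = "osteo_domain_error")
  # non-increasing on a grid, values in [0, 1]
  s <- survival_at(ln, seq(0, 20, by = 0.5))
  expect_true(all(diff(s) <= 0))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("the generalized gamma at Q = 1 collapses to its Weibull special case", {
  gg <- survival_fit("generalized_gamma", c(mu = 1.2, sigma = 0.6, Q = 1))
  wb <- survival_fit("weibull", c(shape = 1 / 0.6, scale = exp(1.2)))
  tt <- seq(0.1, 15, by = 0.7)
  expect_equal(survival_at(gg, tt), survival_at(wb, tt), tolerance = 1e-10)
})

test_that("transition probabilities follow S(t)/S(t-1) and are constant for exponentials", {
  ex <- survival_fit("exponential", c(rate = 0.1))
  expect_equal(transition_probability(ex, 1), 1 - exp(-0.1))
  expect_equal(transition_probability(ex, c(1, 5, 20)),
               rep(1 - exp(-0.1), 3))
  ln <- survival_fit("lognormal", c(meanlog = 0, sdlog = 1))
  expect_equal(transition_probability(ln, 1), 0.5)
  expect_equal(transition_probability(ln, 3, type = "stay") +
                 transition_probability(ln, 3, type = "leave"), 1)
  # no events: S identically 1
  none <- survival_fit("exponential", c(rate = 0))
  expect_equal(transition_probability(none, 4), 0)
  expect_error(transition_probability(ln, 0), class = "osteo_domain_error")
  # absorbed state: survival numerically zero before the requested cycle
  sharp <- survival_fit("lognormal", c(meanlog = 0, sdlog = 1e-9))
  expect_error(transition_probability(sharp, 40),
               class = "osteo_absorbed_error")
})

test_that("survival_at agrees with numeric integration of the hazard", {
  for (fit in list(survival_fit("weibull", c(shape = 1.3, scale = 5)),
                   survival_fit("lognormal", c(meanlog = 1, sdlog = 0.5)))) {
    haz <- function(u) {
      eps <- 1e-7
      s <- survival_at(fit, u)
      (survival_at(fit, u) - survival_at(fit, u + eps)) / (eps * s)
    }
    for (t_end in c(1, 3, 8)) {
      cumhaz <- stats::integrate(haz, 0, t_end, rel.tol = 1e-10,
                                 subdivisions = 500L)$value
      expect_equal(survival_at(fit, t_end), exp(-cumhaz), tolerance = 1e-6)
    }
  }
})

test_that("the full pipeline recovers the generating family for most distributions", {
  cases <- list(
    exponential = c(rate = 0.15),
    weibull = c(shape = 1.6, scale = 6),
    gompertz = c(shape = 0.12, rate = 0.04),
    loglogistic = c(shape = 2.2, scale = 5),
    lognormal = c(meanlog = 1.2, sdlog = 0.6),
    generalized_gamma = c(mu = 1.2, sigma = 0.6, Q = 2)
  )
  hits <- 0L
  for (d in names(cases)) {
    mk <- make_km(d, cases[[d]], n = 2000, censor_time = 12, seed = 11)
    ipd <- reconstruct_ipd(mk$km)
    best <- select_best(suppressWarnings(fit_all_parametric(ipd)))
    if (identical(best$distribution, d)) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})
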
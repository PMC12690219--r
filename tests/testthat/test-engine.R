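# Parameters with every stochastic event switched off: no fractures, no
# cancer transitions, no background deaths.
null_params <- function(base = reduced_params()) {
  p <- unclass(base)
  for (s in names(p$fracture_rate_curves)) p$fracture_rate_curves[[s]]$a <- 0
  p$cancer_transition_fits <- lapply(p$cancer_transition_fits, function(f) {
    list(distribution = "exponential", params = list(rate = 0))
  })
  p$background_mortality$qx <- c(rep(0, nrow(p$background_mortality) - 1L), 1)
  osteo_params(p)
}

one_patient <- function(params, tscore = -1) {
  osteocea:::new_engine_state(make_toy_cohort(1, params, tscore = tscore))
}

u_none <- list(cancer = 0.999, hip = 0.999, vertebral = 0.999, other = 0.999,
               bedridden = 0.999, death = 0.999, adherence = 0.5)

test_that("a cycle with no events only advances BMD, accrual and the clock", {
  p <- null_params()
  st <- builtin_strategies()[1, ]
  s0 <- one_patient(p)
  s1 <- simulate_cycle(s0, st, p, cycle = 0, u = u_none)
  expect_true(s1$alive)
  expect_identical(sum(s1$cnt), 0L)
  expect_identical(s1$cancer, 1L)
  expect_false(s1$bed)
  expect_identical(s1$ly, 1)
  expect_gt(s1$qaly, 0)
  expect_identical(s1$cost, 0)
})

test_that("a dead patient cannot be advanced", {
  p <- null_params()
  s0 <- one_patient(p)
  s0$alive <- FALSE
  expect_error(simulate_cycle(s0, builtin_strategies()[1, ], p),
               class = "osteo_contract_error")
})

test_that("after a hip fracture with certain bedridden transition, no further fractures occur", {
  p <- unclass(null_params())
  p$fracture_rate_curves$hip$a <- 100   # certain hip fracture at any age
  p$p_bedridden_after_hip <- 1
  p <- osteo_params(p)
  st <- builtin_strategies()[1, ]
  s <- one_patient(p)
  u_fx <- modifyList(u_none, list(hip = 1e-9, bedridden = 1e-9))
  s <- simulate_cycle(s, st, p, cycle = 0, u = u_fx)
  expect_identical(unname(s$cnt[1, "hip"]), 1L)
  expect_true(s$bed)
  # later cycles: even a certain-fracture draw cannot fire in the
  # bedridden state
  for (cyc in 1:3) s <- simulate_cycle(s, st, p, cycle = cyc, u = u_fx)
  expect_identical(unname(s$cnt[1, "hip"]), 1L)
})

test_that("death is absorbing and forfeits that cycle's utility", {
  p <- unclass(null_params())
  p$background_mortality$qx <- rep(1, nrow(p$background_mortality))
  p <- osteo_params(p)
  s <- one_patient(p)
  s <- simulate_cycle(s, builtin_strategies()[1, ], p, cycle = 0,
                      u = modifyList(u_none, list(death = 1e-9)))
  expect_false(s$alive)
  expect_identical(s$qaly, 0)
  expect_identical(s$ly, 0)
})

test_that("with unit utility, no discounting and no mortality, a 10-year run accrues exactly 10 QALYs", {
  p <- unclass(null_params())
  p$discount_rate <- 0
  p$utilities$baseline_by_age$utility <- rep(1, 4)
  p$utilities$cancer_state <- list(disease_free = 1, locoregional = 1,
                                   contralateral = 1,
                                   distant_metastasis = 1)
  p <- osteo_params(p)
  res <- run_cohort(50, builtin_strategies()[1, ], p, seed = 3,
                    horizon = 10, keep_patients = TRUE)
  expect_true(all(res$patients$qaly == 10))
  expect_true(all(res$patients$cost == 0))
  expect_true(all(res$patients$ly == 10))
})

test_that("with fractures and cancer switched off, life expectancy matches the life-table oracle", {
  p <- unclass(reduced_params())
  for (s in names(p$fracture_rate_curves)) p$fracture_rate_curves[[s]]$a <- 0
  p$cancer_transition_fits <- lapply(p$cancer_transition_fits, function(f) {
    list(distribution = "exponential", params = list(rate = 0))
  })
  p <- osteo_params(p)
  n <- 20000
  res <- run_cohort(n, builtin_strategies()[1, ], p, seed = 5,
                    keep_patients = TRUE)
  target <- life_table_ly(p)
  se <- sd(res$patients$ly) / sqrt(n)
  expect_lt(abs(res$summary$mean_ly - target), 3 * se)
})

test_that("identical runs are bit-identical and streams are shared across strategies", {
  p <- default_params()
  st <- builtin_strategies()
  a <- run_cohort(2000, st[2, ], p, seed = 9)
  b <- run_cohort(2000, st[2, ], p, seed = 9)
  expect_identical(a$summary, b$summary)
  expect_identical(a$survival, b$survival)
})

test_that("under common random numbers, strategies with no treatment effect leave event histories unchanged", {
  p <- unclass(default_params())
  p$treatment_rr$alendronate <- list(hip = 1, vertebral = 1, other = 1)
  p$adherence <- 1
  p <- osteo_params(p)
  res <- run_strategies(p, builtin_strategies()[c(1, 6), ], n = 4000,
                        seed = 13, keep_patients = TRUE)
  a <- res$outcomes$no_intervention$patients
  b <- res$outcomes$universal_alendronate$patients
  expect_identical(a$any_fracture, b$any_fracture)
  expect_identical(a$ly, b$ly)
  # costs still differ through the drug spend
  expect_gt(sum(b$cost), sum(a$cost))
})

test_that("survival output is non-increasing and cumulative fracture incidence non-decreasing", {
  p <- default_params()
  res <- run_cohort(3000, builtin_strategies()[1, ], p, seed = 17)
  expect_true(all(diff(res$survival$surviving) <= 0))
  expect_true(all(diff(res$cumulative_fracture$incidence) >= 0))
  expect_true(all(res$survival$surviving >= 0))
})

test_that("discounting can only lose QALYs and both stay below the horizon", {
  p <- default_params()
  res <- run_cohort(2000, builtin_strategies()[1, ], p, seed = 19,
                    horizon = 10, keep_patients = TRUE)
  expect_true(all(res$patients$qaly <= res$patients$ly + 1e-9))
  expect_true(all(res$patients$ly <= 10))
  p0 <- with_param(p, "discount_rate", 0)
  res0 <- run_cohort(2000, builtin_strategies()[1, ], p0, seed = 19,
                     horizon = 10)
  expect_gt(res0$summary$mean_qaly, res$summary$mean_qaly)
})

test_that("run_cohort rejects invalid sizes", {
  expect_error(run_cohort(0, builtin_strategies()[1, ], default_params(),
                          seed = 1),
               class = "osteo_input_error")
})
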
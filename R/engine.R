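# First-order Monte Carlo engine over the combined cancer-fracture state
# space. All patients enter at the same age, so every age-indexed input is a
# per-cycle scalar; patient heterogeneity enters through the BMD T-score,
# fracture history, treatment status and the cancer state clocks.
#
# Within-cycle event order (results depend on it, so it is fixed):
#   1 strategy decision (screen / start treatment, adherence draw)
#   2 cancer transition at the current time-in-state (clock resets on entry)
#   3 fracture events per site (suppressed in the bedridden state); a hip
#     fracture triggers the bedridden draw
#   4 death: distant metastasis dies through its fitted survival curve in
#     step 2; everyone else faces background mortality times the hip
#     relative hazard when there is a prior hip fracture
#   5 BMD update (AI loss during the AI course, natural loss after)
#   6 cost and utility accrual, discounted at 1/(1+r)^cycle (cycle 0
#     undiscounted); death during the cycle forfeits that cycle's utility
#     but keeps event costs (DXA, drug, acute fracture) incurred before it
#   7 age + 1, cycle + 1

CANCER_STATES <- c("disease_free", "locoregional", "contralateral",
                   "distant_metastasis")

# Common-random-number streams keyed by event channel; each channel is an
# n x cycles matrix plus one adherence draw per patient. Strategies re-use
# the same streams so incremental results are paired.
make_crn_streams <- function(n, n_cycles, seed) {
  set.seed(as.integer(seed))
  channels <- c("cancer", "hip", "vertebral", "other", "bedridden", "death")
  streams <- lapply(channels, function(ch) {
    matrix(runif(n * n_cycles), nrow = n, ncol = n_cycles)
  })
  names(streams) <- channels
  streams$adherence <- runif(n)
  streams
}

# Everything that does not depend on patient state, tabulated per cycle.
engine_precompute <- function(strategy, params, n_cycles,
                              perspective = "healthcare") {
  ages <- params$start_age + seq_len(n_cycles) - 1L
  fits <- lapply(params$cancer_transition_fits, function(f) {
    if (inherits(f, "osteo_survfit")) f else
      survival_fit(f$distribution, unlist(f$params))
  })
  leave <- lapply(fits, function(f) {
    s <- survival_at(f, 0:n_cycles)
    ifelse(s[-length(s)] > 0, 1 - s[-1] / s[-length(s)], 1)
  })
  drug <- strategy$drug
  trt <- if (!is.na(drug)) params$treatment_rr[[drug]] else
    list(hip = 1, vertebral = 1, other = 1)
  duration <- if (!is.na(strategy$treatment_duration)) {
    strategy$treatment_duration
  } else if (!is.na(drug)) params$treatment_duration[[drug]] else 0
  residual <- if (!is.na(drug)) params$residual_duration[[drug]] %||% 0 else 0
  adherence <- if (!is.na(strategy$adherence)) strategy$adherence else
    params$adherence

  curves <- lapply(fracture_sites(), function(s) {
    cf <- unlist(params$fracture_rate_curves[[s]])
    cf[["a"]] * exp(cf[["b"]] * ages) * params$fracture_rate_scale[[s]]
  })
  names(curves) <- fracture_sites()

  u <- params$utilities
  list(
    ages = ages,
    leave = leave,
    qx = age_lookup(params$background_mortality, ages, "qx"),
    hip_hr = age_lookup(params$hip_fracture_mortality_hr, ages, "hr"),
    mean_t = age_lookup(params$zscore_reference, ages, "mean_tscore"),
    sd_t = age_lookup(params$zscore_reference, ages, "sd_tscore"),
    nat_loss = age_lookup(params$bmd_loss_natural, ages, "loss"),
    u_age = age_lookup(u$baseline_by_age, ages, "utility"),
    curves = curves,
    log_g = vapply(params$gradient_rr_per_sd[fracture_sites()], log,
                   numeric(1)),
    rr_subsq = unlist(params$rr_subsequent_fracture[fracture_sites()]),
    trt_rr = unlist(trt[fracture_sites()]),
    duration = duration,
    residual = residual,
    adherence = adherence,
    drug_cost = if (!is.na(drug)) params$costs$drug_annual[[drug]] else 0,
    disc = discount_factor(seq_len(n_cycles) - 1L, params$discount_rate),
    societal = identical(perspective, "societal"),
    u_state = unlist(params$utilities$cancer_state[CANCER_STATES]),
    u_fx1 = unlist(u$fracture_multiplier_first[fracture_sites()]),
    u_fx2 = unlist(u$fracture_multiplier_subsequent[fracture_sites()]),
    u_bed = u$bedridden,
    u_form = u$fracture_decrement_form,
    costs = params$costs,
    ai_years = params$ai_years
  )
}

new_engine_state <- function(cohort) {
  n <- nrow(cohort)
  list(
    n = n,
    cancer = rep(1L, n),            # index into CANCER_STATES
    tis = rep(0L, n),               # completed cycles in current state
    alive = rep(TRUE, n),
    bed = rep(FALSE, n),
    tscore = cohort$tscore,
    cnt = matrix(0L, n, 3L, dimnames = list(NULL, fracture_sites())),
    anyfx = cohort$prior_fracture %||% rep(FALSE, n),
    status = rep(0L, n),            # 0 never 1 active 2 completed 3 nonadherent
    start_cycle = rep(NA_integer_, n),
    stop_cycle = rep(NA_integer_, n),
    cost = rep(0, n), qaly = rep(0, n), ly = rep(0, n),
    screens = rep(0L, n), complex = rep(0L, n)
  )
}

# Advance every live patient by one cycle. `U` carries this cycle's uniform
# draws; `cyc` is 0-based.
sim_cycle_core <- function(st, cyc, strategy, pre, U) {
  i <- cyc + 1L
  alive0 <- st$alive
  if (!any(alive0)) return(st)

  # 1 --- strategy decision
  dec <- decide_vec(strategy, cyc, st$tscore, st$status)
  dec$screen <- dec$screen & alive0
  dec$start_treatment <- dec$start_treatment & alive0
  st$screens <- st$screens + as.integer(dec$screen)
  starting <- dec$start_treatment
  adherent <- starting & U$adherence <= pre$adherence
  st$status[adherent] <- 1L
  st$status[starting & !adherent] <- 3L
  st$start_cycle[starting] <- cyc
  st$stop_cycle[adherent] <- cyc + pre$duration

  # 2 --- cancer transition (time-in-state clock, resets on entry)
  t_idx <- pmin(st$tis + 1L, length(pre$leave[[1]]))
  u <- U$cancer
  moved <- rep(FALSE, st$n)
  died_cancer <- rep(FALSE, st$n)
  dfs <- alive0 & st$cancer == 1L
  if (any(dfs)) {
    p1 <- pre$leave$dfs_to_lrs[t_idx]
    p2 <- pre$leave$dfs_to_crs[t_idx]
    to_lrs <- dfs & u < p1
    to_crs <- dfs & !to_lrs & u < pmin(p1 + p2, 1)
    st$cancer[to_lrs] <- 2L
    st$cancer[to_crs] <- 3L
    moved <- moved | to_lrs | to_crs
  }
  lrs <- alive0 & st$cancer == 2L & !moved
  if (any(lrs)) {
    go <- lrs & u < pre$leave$lrs_to_dm[t_idx]
    st$cancer[go] <- 4L
    moved <- moved | go
  }
  crs <- alive0 & st$cancer == 3L & !moved
  if (any(crs)) {
    go <- crs & u < pre$leave$crs_to_dm[t_idx]
    st$cancer[go] <- 4L
    moved <- moved | go
  }
  dm <- alive0 & st$cancer == 4L & !moved
  if (any(dm)) {
    died_cancer <- dm & u < pre$leave$dm_to_death[t_idx]
  }
  st$tis <- ifelse(moved, 0L, st$tis + 1L)

  # 3 --- fracture events (not in the bedridden state, not if already dead)
  at_risk <- alive0 & !died_cancer & !st$bed
  z <- (st$tscore - pre$mean_t[i]) / pre$sd_t[i]
  trt_mult <- function(site_idx) {
    m <- rep(1, st$n)
    rr <- pre$trt_rr[[site_idx]]
    act <- st$status == 1L
    m[act] <- rr
    comp <- st$status == 2L
    if (any(comp)) {
      t_off <- cyc - st$stop_cycle[comp] + 0.5
      frac <- if (pre$residual > 0) pmin(pmax(t_off, 0) / pre$residual, 1)
              else as.numeric(t_off > 0)
      m[comp] <- rr + (1 - rr) * frac
    }
    m
  }
  events <- matrix(FALSE, st$n, 3L)
  for (s_i in 1:3) {
    site <- fracture_sites()[s_i]
    rate <- pre$curves[[site]][i] * exp(-z * pre$log_g[[s_i]]) *
      trt_mult(s_i)
    if (site != "vertebral") {
      rate <- rate * ifelse(st$anyfx, pre$rr_subsq[[s_i]], 1)
    }
    p <- 1 - exp(-rate)
    events[, s_i] <- at_risk & U[[site]] < p
  }
  n_events <- rowSums(events)
  st$complex <- st$complex + as.integer(n_events >= 2)
  st$cnt <- st$cnt + events
  hip_now <- events[, 1L]
  new_bed <- hip_now & U$bedridden < pre$p_bedridden
  st$anyfx <- st$anyfx | n_events > 0

  # 4 --- death (background x hip excess; DM handled by its fitted curve)
  prior_hip <- st$cnt[, 1L] > 0L
  q <- pmin(pre$qx[i] * ifelse(prior_hip, pre$hip_hr[i], 1), 1)
  non_dm <- alive0 & !died_cancer & st$cancer != 4L
  dm_alive <- alive0 & !died_cancer & st$cancer == 4L
  died_bg <- non_dm & U$death < q
  died <- died_cancer | died_bg
  st$alive <- alive0 & !died

  # 5 --- BMD update
  loss <- if (cyc < pre$ai_years) pre$ai_loss else pre$nat_loss[i]
  st$tscore <- st$tscore - loss

  # 6 --- accrual
  df <- pre$disc[i]
  co <- pre$costs
  cost <- rep(0, st$n)
  cost <- cost + as.numeric(dec$screen) * co$dxa
  on_drug <- st$status == 1L & alive0
  first_nonadh <- st$status == 3L & !is.na(st$start_cycle) &
    st$start_cycle == cyc
  cost <- cost + as.numeric(on_drug | first_nonadh) * pre$drug_cost
  acute <- unlist(co$fracture_acute[fracture_sites()])
  cost <- cost + events %*% acute
  surv <- st$alive
  prior_cnt <- st$cnt - events   # history before this cycle
  mgmt <- unlist(co$fracture_management_annual[fracture_sites()])
  cost <- cost + ((prior_cnt > 0) %*% mgmt) * as.numeric(surv & !st$bed)
  cost <- cost + as.numeric(st$bed & surv) * co$long_term_care_annual
  if (pre$societal) {
    ind <- co$indirect
    cost <- cost + n_events * ind$nonmedical_first_year
    cost <- cost + as.numeric(n_events > 0) * ind$caregiver_annual
    cost <- cost + as.numeric(st$bed & surv) * ind$caregiver_annual
  }
  cost[!alive0] <- 0
  st$cost <- st$cost + as.numeric(cost) * df

  u_cyc <- pre$u_age[i] * unname(pre$u_state[st$cancer])
  had_prior <- prior_cnt > 0
  for (s_i in 1:3) {
    m1 <- pre$u_fx1[[s_i]]; m2 <- pre$u_fx2[[s_i]]
    if (identical(pre$u_form, "additive")) {
      u_cyc <- u_cyc - pre$u_age[i] *
        ((1 - m1) * events[, s_i] +
           (1 - m2) * (had_prior[, s_i] & !events[, s_i]))
    } else {
      mult <- ifelse(events[, s_i], m1,
                     ifelse(had_prior[, s_i], m2, 1))
      u_cyc <- u_cyc * mult
    }
  }
  bed_state <- st$bed | new_bed
  u_cyc[bed_state] <- pre$u_bed
  gain <- ifelse(surv, pmax(u_cyc, -1), 0)
  st$qaly <- st$qaly + as.numeric(gain) * df
  st$ly <- st$ly + as.numeric(surv)

  st$bed <- bed_state
  # completed courses move to 'completed' once the duration has elapsed
  finishing <- st$status == 1L & !is.na(st$stop_cycle) &
    (cyc + 1L) >= st$stop_cycle
  st$status[finishing] <- 2L
  st
}

#' Simulate one cycle for a single patient
#'
#' Thin single-patient wrapper around the vectorized engine step, mainly
#' for inspection and testing. The within-cycle event order is: strategy
#' decision, cancer transition, fracture events, death, BMD update,
#' discounted accrual.
#'
#' @param patient A patient state as produced by [make_toy_cohort()] /
#'   internal engine state (a list; see `new_engine_state`).
#' @param strategy A one-row `osteo_strategy`.
#' @param params An [osteo_params] object.
#' @param cycle 0-based cycle index.
#' @param u Named list of uniform draws for the cycle (`cancer`, `hip`,
#'   `vertebral`, `other`, `bedridden`, `death`, `adherence`); defaults to
#'   fresh `runif` draws.
#' @param perspective `"healthcare"` or `"societal"`.
#' @return The updated patient state list.
#' @export
simulate_cycle <- function(patient, strategy, params, cycle = 0L,
                           u = NULL, perspective = "healthcare") {
  if (!isTRUE(all(patient$alive))) {
    abort("simulate_cycle requires a live patient",
          class = "osteo_contract_error")
  }
  n_cycles <- params$max_age - params$start_age
  pre <- engine_precompute(strategy, params, n_cycles, perspective)
  pre$p_bedridden <- params$p_bedridden_after_hip
  pre$ai_loss <- params$bmd_loss_on_ai
  if (is.null(u)) {
    u <- list(cancer = runif(1), hip = runif(1), vertebral = runif(1),
              other = runif(1), bedridden = runif(1), death = runif(1),
              adherence = runif(1))
  }
  sim_cycle_core(patient, as.integer(cycle), strategy, pre, u)
}

resolve_horizon <- function(params, horizon) {
  if (identical(horizon, "lifetime")) {
    params$max_age - params$start_age
  } else {
    min(as.integer(horizon), params$max_age - params$start_age)
  }
}

#' Run a cohort through one strategy
#'
#' First-order Monte Carlo simulation of `n` individual trajectories from
#' the starting age to death or the horizon. Reruns with identical
#' `(strategy, params, n, seed)` are bit-identical, and the random streams
#' are keyed by patient and event channel so that runs under different
#' strategies share their pre-decision event draws (common random numbers).
#'
#' @param n Number of simulated patients (`>= 1`).
#' @param strategy A one-row `osteo_strategy`.
#' @param params An [osteo_params] object.
#' @param seed Integer seed.
#' @param horizon `"lifetime"` or a number of years.
#' @param perspective `"healthcare"` (default) or `"societal"`.
#' @param cohort,streams Optional pre-built cohort tibble and CRN streams
#'   (as used by [run_strategies()] to share them across strategies).
#' @param keep_patients Keep the per-patient discounted cost/QALY vectors?
#' @return An `osteo_outcome` list: `summary` (one-row tibble with mean/SE
#'   discounted cost and QALY, mean life-years, event counts), `survival`
#'   (proportion alive by year), `cumulative_fracture` (proportion with any
#'   fracture by year), and optionally `patients`.
#' @export
run_cohort <- function(n, strategy, params, seed, horizon = "lifetime",
                       perspective = "healthcare", cohort = NULL,
                       streams = NULL, keep_patients = FALSE) {
  stopifnot(inherits(params, "osteo_params"), nrow(strategy) == 1L)
  if (n < 1) abort("n must be >= 1", class = "osteo_input_error")
  n_cycles <- resolve_horizon(params, horizon)
  if (is.null(cohort)) cohort <- make_toy_cohort(n, params, seed = seed)
  if (is.null(streams)) {
    streams <- make_crn_streams(nrow(cohort), n_cycles, seed + 1L)
  }
  pre <- engine_precompute(strategy, params, n_cycles, perspective)
  pre$p_bedridden <- params$p_bedridden_after_hip
  pre$ai_loss <- params$bmd_loss_on_ai

  st <- new_engine_state(cohort)
  alive_by_year <- numeric(n_cycles)
  fx_by_year <- numeric(n_cycles)
  baseline_fx <- st$anyfx
  for (cyc in seq_len(n_cycles) - 1L) {
    U <- list(cancer = streams$cancer[, cyc + 1L],
              hip = streams$hip[, cyc + 1L],
              vertebral = streams$vertebral[, cyc + 1L],
              other = streams$other[, cyc + 1L],
              bedridden = streams$bedridden[, cyc + 1L],
              death = streams$death[, cyc + 1L],
              adherence = streams$adherence)
    st <- sim_cycle_core(st, cyc, strategy, pre, U)
    alive_by_year[cyc + 1L] <- mean(st$alive)
    fx_by_year[cyc + 1L] <- mean(st$anyfx & !baseline_fx)
    if (!any(st$alive)) {
      if (cyc + 2L <= n_cycles) {
        alive_by_year[(cyc + 2L):n_cycles] <- 0
        fx_by_year[(cyc + 2L):n_cycles] <- fx_by_year[cyc + 1L]
      }
      break
    }
  }

  summary <- tibble(
    strategy = strategy$name,
    n = st$n,
    mean_cost = mean(st$cost),
    se_cost = sd(st$cost) / sqrt(st$n),
    mean_qaly = mean(st$qaly),
    se_qaly = sd(st$qaly) / sqrt(st$n),
    mean_ly = mean(st$ly),
    fractures_hip = sum(st$cnt[, "hip"]),
    fractures_vertebral = sum(st$cnt[, "vertebral"]),
    fractures_other = sum(st$cnt[, "other"]),
    complex_fracture_cycles = sum(st$complex),
    n_bedridden = sum(st$bed),
    n_screens = sum(st$screens),
    n_treated = sum(st$status %in% c(1L, 2L)),
    n_nonadherent = sum(st$status == 3L),
    deaths = sum(!st$alive)
  )
  out <- list(
    summary = summary,
    survival = tibble(year = seq_len(n_cycles), surviving = alive_by_year),
    cumulative_fracture = tibble(year = seq_len(n_cycles),
                                 incidence = fx_by_year),
    strategy = strategy
  )
  if (keep_patients) {
    out$patients <- tibble(cost = st$cost, qaly = st$qaly, ly = st$ly,
                           any_fracture = st$anyfx,
                           treated = st$status %in% c(1L, 2L))
  }
  class(out) <- "osteo_outcome"
  out
}

#' @export
print.osteo_outcome <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<osteo_outcome> %s: n=%d, cost $%.2f (SE %.2f), QALY %.4f (SE %.5f)\n",
              s$strategy, s$n, s$mean_cost, s$se_cost, s$mean_qaly,
              s$se_qaly))
  invisible(x)
}

#' Run a set of strategies under common random numbers
#'
#' Builds the cohort and the per-channel random streams once, then runs
#' every strategy against them, so strategies differ only through their
#' screening/treatment decisions.
#'
#' @param params An [osteo_params] object.
#' @param strategies An `osteo_strategy` tibble (default
#'   [builtin_strategies()]).
#' @param n Patients per strategy.
#' @param seed Integer seed.
#' @inheritParams run_cohort
#' @return An `osteo_outcomes` object: `summary` tibble (one row per
#'   strategy) plus the individual `osteo_outcome` objects.
#' @export
run_strategies <- function(params, strategies = builtin_strategies(),
                           n = 10000, seed = 1, horizon = "lifetime",
                           perspective = "healthcare",
                           keep_patients = FALSE, prior_fracture = FALSE) {
  n_cycles <- resolve_horizon(params, horizon)
  cohort <- make_toy_cohort(n, params, seed = seed,
                            prior_fracture = prior_fracture)
  streams <- make_crn_streams(n, n_cycles, seed + 1L)
  outcomes <- lapply(seq_len(nrow(strategies)), function(k) {
    run_cohort(n, strategies[k, ], params, seed, horizon = horizon,
               perspective = perspective, cohort = cohort,
               streams = streams, keep_patients = keep_patients)
  })
  names(outcomes) <- strategies$name
  res <- list(summary = bind_rows(lapply(outcomes, `[[`, "summary")),
              outcomes = outcomes, n = n, seed = seed, horizon = horizon)
  class(res) <- "osteo_outcomes"
  res
}

#' @export
print.osteo_outcomes <- function(x, ...) {
  cat(sprintf("<osteo_outcomes> %d strategies, n=%d per strategy\n",
              nrow(x$summary), x$n))
  print(x$summary[, c("strategy", "mean_cost", "mean_qaly", "mean_ly")])
  invisible(x)
}
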
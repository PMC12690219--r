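# Shared fixtures built in code.

.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (is.null(.fixture_env$dp)) .fixture_env$dp <- make_default_params()
  .fixture_env$dp
}

default_params <- function() default_fixture()$params

with_param <- function(params, path, value) {
  osteo_params(osteocea:::param_set(unclass(params), path, value))
}

# Heterogeneity-free reduction of the model: exponential (memoryless) cancer
# transitions, frozen BMD, no fracture-history effects, no bedridden state,
# no hip excess mortality, perfect adherence. Under these conditions every
# patient faces the same per-cycle probabilities, so the microsimulation
# mean equals a deterministic cohort-Markov computation.
reduced_params <- function(base = default_params(),
                           rates = c(dfs_to_lrs = 0.012, dfs_to_crs = 0.006,
                                     lrs_to_dm = 0.15, crs_to_dm = 0.10,
                                     dm_to_death = 0.30)) {
  p <- unclass(base)
  p$cancer_transition_fits <- lapply(as.list(rates), function(r) {
    list(distribution = "exponential", params = list(rate = r))
  })
  p$bmd_baseline$sd_tscore <- rep(0, nrow(p$bmd_baseline))
  p$bmd_loss_on_ai <- 0
  p$bmd_loss_natural$loss <- rep(0, nrow(p$bmd_loss_natural))
  p$rr_subsequent_fracture <- list(hip = 1, vertebral = 1, other = 1)
  p$p_bedridden_after_hip <- 0
  p$hip_fracture_mortality_hr$hr <- rep(1, nrow(p$hip_fracture_mortality_hr))
  p$utilities$fracture_multiplier_subsequent <-
    list(hip = 1, vertebral = 1, other = 1)
  p$costs$fracture_management_annual <- list(hip = 0, vertebral = 0,
                                             other = 0)
  p$costs$long_term_care_annual <- 0
  p$adherence <- 1
  osteo_params(p)
}

# Independent deterministic cohort-Markov oracle for the reduction above:
# plain matrix iteration over (DFS, LRS, CRS, DM, dead) occupancy with
# expected-value accrual. Mirrors the engine's within-cycle event order but
# shares no code with it.
markov_oracle <- function(params, strategy_kind = c("none", "universal"),
                          n_cycles = NULL) {
  strategy_kind <- match.arg(strategy_kind)
  p <- unclass(params)
  if (is.null(n_cycles)) n_cycles <- p$max_age - p$start_age
  rates <- vapply(p$cancer_transition_fits,
                  function(f) unlist(f$params)[["rate"]], numeric(1))
  leave <- 1 - exp(-rates)   # constant hazards
  ages <- p$start_age + seq_len(n_cycles) - 1L
  qx <- sapply(ages, function(a) {
    tab <- p$background_mortality
    tab$qx[findInterval(a, tab$age)]
  })
  step_lookup <- function(tab, col) {
    sapply(ages, function(a) tab[[col]][findInterval(a, tab$age)])
  }
  mean_t <- step_lookup(p$zscore_reference, "mean_tscore")
  sd_t <- step_lookup(p$zscore_reference, "sd_tscore")
  u_age <- step_lookup(p$utilities$baseline_by_age, "utility")
  t0 <- p$bmd_baseline$mean_tscore[findInterval(p$start_age,
                                                p$bmd_baseline$age)]
  sites <- c("hip", "vertebral", "other")
  drug <- "alendronate"
  duration <- p$treatment_duration[[drug]]
  residual <- p$residual_duration[[drug]]

  occ <- c(1, 0, 0, 0, 0)   # DFS, LRS, CRS, DM, dead
  cost <- 0; qaly <- 0; ly <- 0
  for (cyc in seq_len(n_cycles) - 1L) {
    i <- cyc + 1L
    df <- 1 / (1 + p$discount_rate)^cyc
    q <- qx[i]
    p1 <- leave[["dfs_to_lrs"]]; p2 <- leave[["dfs_to_crs"]]
    pl <- leave[["lrs_to_dm"]]; pc <- leave[["crs_to_dm"]]
    pd <- leave[["dm_to_death"]]
    # transition + death layering exactly as the engine orders it:
    # movers to DM skip both death draws in their transition cycle
    M <- rbind(
      c((1 - p1 - p2) * (1 - q), p1 * (1 - q), p2 * (1 - q), 0, q),
      c(0, (1 - pl) * (1 - q), 0, pl, (1 - pl) * q),
      c(0, 0, (1 - pc) * (1 - q), pc, (1 - pc) * q),
      c(0, 0, 0, 1 - pd, pd),
      c(0, 0, 0, 0, 1))
    occ_next <- as.numeric(occ %*% M)

    # fracture probabilities (identical for everyone; frozen BMD)
    z <- (t0 - mean_t[i]) / sd_t[i]
    trt <- vapply(sites, function(s) {
      if (strategy_kind == "none") return(1)
      rr <- p$treatment_rr[[drug]][[s]]
      if (cyc < duration) rr else {
        t_off <- cyc - duration + 0.5
        if (residual > 0) rr + (1 - rr) * min(t_off / residual, 1) else 1
      }
    }, numeric(1))
    # treatment RR applies on the rate scale
    pfx <- vapply(seq_along(sites), function(k) {
      s <- sites[k]
      cf <- unlist(p$fracture_rate_curves[[s]])
      g <- p$gradient_rr_per_sd[[s]]
      r <- cf[["a"]] * exp(cf[["b"]] * ages[i]) * p$fracture_rate_scale[[s]] *
        g^(-z) * trt[k]
      1 - exp(-r)
    }, numeric(1))

    at_risk <- occ[1] + occ[2] + occ[3] + occ[4] * (1 - pd)
    exp_events <- at_risk * pfx

    acute <- unlist(p$costs$fracture_acute[sites])
    c_cyc <- sum(exp_events * acute)
    if (strategy_kind == "universal" && cyc < duration) {
      c_cyc <- c_cyc + sum(occ[1:4]) * p$costs$drug_annual[[drug]]
    }
    cost <- cost + c_cyc * df

    u_state <- unlist(p$utilities$cancer_state)
    m1 <- unlist(p$utilities$fracture_multiplier_first[sites])
    fx_mult <- prod(1 - pfx * (1 - m1))
    survivors <- occ_next[1:4]
    qaly <- qaly + df * u_age[i] * sum(survivors * u_state) * fx_mult
    ly <- ly + sum(survivors)
    occ <- occ_next
  }
  list(cost = cost, qaly = qaly, ly = ly)
}

# Life-table expectancy oracle: expected whole-years lived from the start
# age under the background mortality table alone.
life_table_ly <- function(params, n_cycles = NULL) {
  p <- unclass(params)
  if (is.null(n_cycles)) n_cycles <- p$max_age - p$start_age
  ages <- p$start_age + seq_len(n_cycles) - 1L
  qx <- sapply(ages, function(a) {
    tab <- p$background_mortality
    tab$qx[findInterval(a, tab$age)]
  })
  sum(cumprod(1 - qx))
}
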
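#' Convert an incidence rate to a transition probability
#'
#' `p = 1 - exp(-r t)` for a constant rate `r` (events/person-year) over an
#' interval of `t` years. Always below `r * t`, and first-order equal to it
#' for small `r * t`.
#'
#' @param rate Incidence rate(s), events/person-year, `>= 0`.
#' @param interval Interval length in years, `> 0` (default 1, the cycle
#'   length).
#' @return Probabilities in `[0, 1)`.
#' @export
rate_to_probability <- function(rate, interval = 1) {
  if (any(rate < 0)) {
    abort("rate must be non-negative", class = "osteo_domain_error")
  }
  if (any(interval <= 0)) {
    abort("interval must be positive", class = "osteo_domain_error")
  }
  1 - exp(-rate * interval)
}

#' Advance a bone-mineral-density state by one year
#'
#' During aromatase-inhibitor (AI) therapy the femoral-neck T-score drops by
#' the constant AI-specific annual loss; off therapy it drops by the
#' age-specific natural loss (step lookup into `bmd_loss_natural`). Age is
#' incremented by one year.
#'
#' @param bmd A list or one-row data frame with `tscore` (SD units) and
#'   `age` (years).
#' @param on_ai Logical: currently on AI therapy?
#' @param params An [osteo_params] object.
#' @return The updated BMD state (same shape as the input).
#' @export
update_bmd <- function(bmd, on_ai, params) {
  loss <- if (isTRUE(on_ai)) {
    params$bmd_loss_on_ai
  } else {
    age_lookup(params$bmd_loss_natural, bmd$age, "loss")
  }
  bmd$tscore <- bmd$tscore - loss
  bmd$age <- bmd$age + 1
  bmd
}

#' Convert a T-score to an age-matched Z-score (and back)
#'
#' T-scores express BMD in standard deviations of the young-adult reference;
#' Z-scores in standard deviations of the age-matched population. With the
#' age-specific population mean and SD expressed in T-score units,
#' `Z = (T - mean_t(age)) / sd_t(age)`. At the young-adult reference age the
#' population mean is 0 and SD 1, so `Z = T` there.
#'
#' @param tscore,zscore Score(s) in SD units.
#' @param age Age(s) in years; must be covered by the reference table.
#' @param params An [osteo_params] object carrying `zscore_reference`.
#' @return The converted score(s); the two functions are exact inverses.
#' @export
tscore_to_zscore <- function(tscore, age, params) {
  ref <- params$zscore_reference
  if (any(age < min(ref$age)) || any(age > max(ref$age) + 25)) {
    abort(sprintf("age outside the Z-score reference range [%g, %g]",
                  min(ref$age), max(ref$age)),
          class = "osteo_range_error")
  }
  (tscore - age_lookup(ref, age, "mean_tscore")) /
    age_lookup(ref, age, "sd_tscore")
}

#' @rdname tscore_to_zscore
#' @export
zscore_to_tscore <- function(zscore, age, params) {
  ref <- params$zscore_reference
  zscore * age_lookup(ref, age, "sd_tscore") +
    age_lookup(ref, age, "mean_tscore")
}

# Vectorized annual fracture rate at the heart of the risk model:
# rate = age-curve(site, age) * scale * gradient^(-Z) * RR_subsequent,
# with the subsequent-fracture multiplier suppressed for vertebral events.
fracture_rate_raw <- function(site, age, zscore, any_prior, params,
                              extra_rr = 1) {
  curve <- unlist(params$fracture_rate_curves[[site]])
  base <- curve[["a"]] * exp(curve[["b"]] * age) *
    params$fracture_rate_scale[[site]]
  g <- params$gradient_rr_per_sd[[site]]
  adj <- g^(-zscore)
  subsq <- if (site == "vertebral") 1 else {
    ifelse(any_prior, params$rr_subsequent_fracture[[site]], 1)
  }
  base * adj * subsq * extra_rr
}

#' Age- and BMD-specific fracture risk
#'
#' The annual fracture incidence rate is the site's age curve (fitted
#' exponential in age, evaluated at the age-matched mean BMD, i.e. Z = 0)
#' multiplied by the gradient of risk per SD of BMD below the age-matched
#' mean (`gradient^(-Z)`), and by the relative risk of repeat fracture when
#' the patient has any prior fracture - except for vertebral fractures,
#' which are exempt from the repeat-fracture multiplier. The per-cycle
#' probability follows from [rate_to_probability()].
#'
#' @param site `"hip"`, `"vertebral"` or `"other"`.
#' @param bmd A list with `tscore` and `age`.
#' @param any_prior Logical: any prior fragility fracture?
#' @param params An [osteo_params] object.
#' @return A one-row tibble with `site`, `annual_rate` and
#'   `cycle_probability`.
#' @export
fracture_rate <- function(site, bmd, any_prior, params) {
  site <- match.arg(site, fracture_sites())
  z <- tscore_to_zscore(bmd$tscore, bmd$age, params)
  r <- fracture_rate_raw(site, bmd$age, z, any_prior, params)
  tibble(site = site, annual_rate = r,
         cycle_probability = rate_to_probability(r, 1))
}

#' Treatment effect on fracture risk, with residual offset
#'
#' On treatment the configured relative risk (RR) applies. After stopping,
#' bisphosphonates retain a residual (offset) effect for a period equal to
#' the treatment duration: the RR rises linearly from the on-treatment
#' value back to 1 over `residual_duration` years, reaching exactly 1 at
#' the end. Drugs with no configured residual revert to RR 1 immediately.
#'
#' @param drug Drug name configured in `params$treatment_rr`.
#' @param site Fracture site.
#' @param years_since_stop Years since the end of the treatment course;
#'   values `<= 0` mean still on treatment.
#' @param params An [osteo_params] object.
#' @return Dimensionless RR(s) in `[configured RR, 1]`, continuous at the
#'   stop time.
#' @export
treatment_rr <- function(drug, site, years_since_stop, params) {
  if (!drug %in% names(params$treatment_rr)) {
    abort(sprintf("drug '%s' is not configured", drug),
          class = "osteo_config_error")
  }
  site <- match.arg(site, fracture_sites())
  rr <- params$treatment_rr[[drug]][[site]]
  residual <- params$residual_duration[[drug]] %||% 0
  t_off <- pmax(years_since_stop, 0)
  frac <- if (residual > 0) pmin(t_off / residual, 1) else as.numeric(t_off > 0)
  rr + (1 - rr) * frac
}
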
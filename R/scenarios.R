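#' Define a scenario
#'
#' Scenarios recombine the base-case analysis over starting age band, risk
#' group (history of falls or of prior fracture), screening interval,
#' adherence, drug, analytic perspective and time horizon.
#'
#' @param start_age_band `"60-64"`, `"65-69"`, `"70-74"` or `"75-79"`;
#'   simulation starts at the band's lower edge with the band's baseline
#'   BMD.
#' @param risk_modifier `"none"`, `"prior_fracture"` (cohort enters with
#'   the any-prior-fracture flag set, and rates are multiplied by the
#'   configured prior-fracture RR) or `"prior_falls"` (rates multiplied by
#'   the falls RR).
#' @param adherence_override Optional adherence proportion (e.g. 0.72 or
#'   0.54).
#' @param drug_override Optional drug replacing alendronate in the treating
#'   strategies.
#' @param perspective `"healthcare"` or `"societal"` (adds indirect
#'   non-medical and caregiver costs).
#' @param horizon `"lifetime"` or `"10y"`.
#' @param screening_interval_override Optional `"2y"` or `"5y"`: periodic
#'   screening strategies switch to that interval.
#' @return A list of class `osteo_scenario`.
#' @export
scenario_spec <- function(start_age_band = "60-64",
                          risk_modifier = "none",
                          adherence_override = NA_real_,
                          drug_override = NA_character_,
                          perspective = "healthcare",
                          horizon = "lifetime",
                          screening_interval_override = NA_character_) {
  start_age_band <- match.arg(start_age_band,
                              c("60-64", "65-69", "70-74", "75-79"))
  risk_modifier <- match.arg(risk_modifier,
                             c("none", "prior_fracture", "prior_falls"))
  perspective <- match.arg(perspective, c("healthcare", "societal"))
  horizon <- match.arg(horizon, c("lifetime", "10y"))
  if (!is.na(screening_interval_override)) {
    screening_interval_override <- match.arg(screening_interval_override,
                                             c("2y", "5y"))
  }
  structure(list(start_age_band = start_age_band,
                 risk_modifier = risk_modifier,
                 adherence_override = adherence_override,
                 drug_override = drug_override,
                 perspective = perspective,
                 horizon = horizon,
                 screening_interval_override = screening_interval_override),
            class = "osteo_scenario")
}

#' Apply a scenario to a parameter set and strategy table
#'
#' Pure: the base inputs are not modified. The identity scenario (all
#' defaults) returns them unchanged.
#'
#' @param base An [osteo_params] object.
#' @param spec An [scenario_spec()].
#' @param strategies An `osteo_strategy` tibble to adjust (default
#'   [builtin_strategies()]).
#' @return A list with `params`, `strategies`, `horizon` (`"lifetime"` or
#'   years), `perspective` and `prior_fracture` (whether the cohort enters
#'   with a fracture history).
#' @export
apply_scenario <- function(base, spec, strategies = builtin_strategies()) {
  stopifnot(inherits(base, "osteo_params"), inherits(spec, "osteo_scenario"))
  p <- unclass(base)
  prior_fracture <- FALSE

  start_age <- as.integer(sub("-.*", "", spec$start_age_band))
  p$start_age <- start_age

  if (spec$risk_modifier != "none") {
    rr <- p$risk_modifiers[[spec$risk_modifier]]
    if (is.null(rr)) {
      abort(sprintf("risk modifier '%s' has no configured relative risk",
                    spec$risk_modifier), class = "osteo_config_error")
    }
    for (s in fracture_sites()) {
      p$fracture_rate_scale[[s]] <- p$fracture_rate_scale[[s]] * rr
    }
    if (spec$risk_modifier == "prior_fracture") prior_fracture <- TRUE
  }
  if (!is.na(spec$adherence_override)) {
    if (is.null(p$adherence)) {
      abort("adherence override without a configured base value",
            class = "osteo_config_error")
    }
    p$adherence <- spec$adherence_override
  }
  strat <- strategies
  if (!is.na(spec$drug_override)) {
    if (!spec$drug_override %in% names(p$treatment_rr)) {
      abort(sprintf("drug override '%s' is not configured",
                    spec$drug_override), class = "osteo_config_error")
    }
    strat$drug[!is.na(strat$drug)] <- spec$drug_override
  }
  if (!is.na(spec$screening_interval_override)) {
    interval <- switch(spec$screening_interval_override,
                       "2y" = "every_2", "5y" = "every_5")
    strat$screening[grepl("^every_", strat$screening)] <- interval
  }
  horizon <- if (spec$horizon == "10y") 10L else "lifetime"
  list(params = osteo_params(p), strategies = strat, horizon = horizon,
       perspective = spec$perspective, prior_fracture = prior_fracture)
}

#' Run a scenario end to end
#'
#' Applies the scenario and runs every adjusted strategy under common
#' random numbers.
#'
#' @inheritParams apply_scenario
#' @param n Patients per strategy.
#' @param seed Integer seed.
#' @return An `osteo_outcomes` object with a `scenario` attribute.
#' @export
run_scenario <- function(base, spec, strategies = builtin_strategies(),
                         n = 10000, seed = 1) {
  sc <- apply_scenario(base, spec, strategies)
  res <- run_strategies(sc$params, sc$strategies, n = n, seed = seed,
                        horizon = sc$horizon, perspective = sc$perspective,
                        prior_fracture = sc$prior_fracture)
  attr(res, "scenario") <- spec
  res
}
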
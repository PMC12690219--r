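#' Define a screening/treatment strategy
#'
#' A strategy couples a DXA screening schedule with a treatment-eligibility
#' rule and a drug. Screening measures the current model T-score without
#' error; a patient starts at most one treatment course per lifetime, and
#' screening stops once treatment has started.
#'
#' @param name Strategy label.
#' @param screening `"none"`, `"once"` (cycle 0 only), or `"every_1"`,
#'   `"every_2"`, `"every_5"` (cycles 0, k, 2k, ...).
#' @param threshold Eligibility rule: `"osteoporosis"` (T-score <= -2.5),
#'   `"osteopenia"` (T-score <= -1.0), `"universal"` (treat everyone at
#'   cycle 0 without screening) or `"never"`.
#' @param drug `"alendronate"`, `"denosumab"`, `"zoledronate"`, or `NA`
#'   when `threshold = "never"`.
#' @param treatment_duration Course length in years; `NA` defers to the
#'   drug's configured duration (alendronate/denosumab 5 y, zoledronate 3 y).
#' @param adherence Optional override of the configured adherence
#'   proportion.
#' @return A one-row tibble of class `osteo_strategy`.
#' @export
strategy_spec <- function(name, screening, threshold, drug = NA_character_,
                          treatment_duration = NA_real_,
                          adherence = NA_real_) {
  screening <- match.arg(screening,
                         c("none", "once", "every_1", "every_2", "every_5"))
  threshold <- match.arg(threshold,
                         c("osteoporosis", "osteopenia", "universal", "never"))
  if ((screening == "none") != (threshold %in% c("universal", "never"))) {
    abort(paste("screening 'none' is valid exactly for thresholds",
                "'universal' and 'never'"), class = "osteo_strategy_error")
  }
  if (threshold != "never" && is.na(drug)) {
    abort("treating strategies need a drug", class = "osteo_strategy_error")
  }
  if (!is.na(treatment_duration) && treatment_duration <= 0) {
    abort("treatment_duration must be positive",
          class = "osteo_strategy_error")
  }
  out <- tibble(name = name, screening = screening, threshold = threshold,
                drug = drug, treatment_duration = treatment_duration,
                adherence = adherence)
  class(out) <- c("osteo_strategy", class(out))
  out
}

threshold_tscore <- function(threshold) {
  switch(threshold, osteoporosis = -2.5, osteopenia = -1.0, NA_real_)
}

screening_cycles <- function(screening, horizon_cycles) {
  switch(screening,
    none = integer(0),
    once = 0L,
    every_1 = seq(0L, horizon_cycles, by = 1L),
    every_2 = seq(0L, horizon_cycles, by = 2L),
    every_5 = seq(0L, horizon_cycles, by = 5L))
}

#' The six base-case strategies
#'
#' No intervention; one-time DXA screening treating osteoporosis
#' (T-score <= -2.5) or osteopenia (T-score <= -1.0); annual DXA screening
#' with the same two eligibility rules; and universal alendronate therapy
#' without screening.
#'
#' @return An `osteo_strategy` tibble with six rows.
#' @export
builtin_strategies <- function() {
  out <- bind_rows(
    strategy_spec("no_intervention", "none", "never"),
    strategy_spec("once_osteoporosis", "once", "osteoporosis", "alendronate"),
    strategy_spec("once_osteopenia", "once", "osteopenia", "alendronate"),
    strategy_spec("annual_osteoporosis", "every_1", "osteoporosis",
                  "alendronate"),
    strategy_spec("annual_osteopenia", "every_1", "osteopenia", "alendronate"),
    strategy_spec("universal_alendronate", "none", "universal", "alendronate")
  )
  class(out) <- c("osteo_strategy", class(out))
  out
}

# Vectorized screening/treatment decision. `trt_status` codes:
# 0 never, 1 active, 2 completed, 3 nonadherent.
decide_vec <- function(strategy, cycle, tscore, trt_status) {
  sched <- screening_cycles(strategy$screening, cycle)
  due <- cycle %in% sched
  screen <- due & trt_status == 0L
  start <- rep(FALSE, length(tscore))
  if (strategy$threshold == "universal") {
    start <- (cycle == 0L) & trt_status == 0L
  } else if (strategy$threshold %in% c("osteoporosis", "osteopenia")) {
    start <- screen & tscore <= threshold_tscore(strategy$threshold)
  }
  list(screen = screen, start_treatment = start)
}

#' Screening/treatment decision for one patient-cycle
#'
#' Applies the strategy's schedule and eligibility rule to a patient's
#' current state: screening fires on schedule only while the patient has
#' never started treatment; treatment starts if the strategy is universal
#' (cycle 0) or a screen finds the T-score at or below the threshold. DXA
#' cost is incurred exactly when a screen happens.
#'
#' @param strategy A one-row `osteo_strategy`.
#' @param patient A list with `tscore` and `trt_status` (one of `"never"`,
#'   `"active"`, `"completed"`, `"nonadherent"`).
#' @param cycle Current cycle (0-based).
#' @return A list with logical `screen`, `start_treatment` and
#'   `dxa_cost_incurred`.
#' @export
decide <- function(strategy, patient, cycle) {
  stopifnot(nrow(strategy) == 1L)
  status <- match(patient$trt_status %||% "never",
                  c("never", "active", "completed", "nonadherent")) - 1L
  d <- decide_vec(strategy, cycle, patient$tscore, status)
  list(screen = d$screen, start_treatment = d$start_treatment,
       dxa_cost_incurred = d$screen)
}
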
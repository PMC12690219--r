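outcome_row <- function(x) {
  if (inherits(x, "osteo_outcome")) x <- x$summary
  stopifnot(is.data.frame(x), nrow(x) == 1L)
  tibble(strategy = x$strategy %||% NA_character_,
         cost = x$mean_cost %||% x$cost,
         qaly = x$mean_qaly %||% x$qaly)
}

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `ICER = (cost_b - cost_a) / (qaly_b - qaly_a)` in $/QALY, with `a` the
#' reference. A comparator that saves money while gaining QALYs is flagged
#' `"dominant"` rather than reported as a negative ratio; one that costs
#' more while losing QALYs is flagged `"dominated"`. A zero QALY difference
#' yields an undefined ICER (`NA` with `undefined = TRUE`).
#'
#' @param a,b One-row outcome summaries (or `osteo_outcome` objects):
#'   `a` is the reference, `b` the comparator.
#' @return A one-row tibble with `delta_cost`, `delta_qaly`, `icer`,
#'   `dominance` and `undefined`.
#' @export
icer <- function(a, b) {
  ra <- outcome_row(a); rb <- outcome_row(b)
  dc <- rb$cost - ra$cost
  dq <- rb$qaly - ra$qaly
  dominance <- NA_character_
  undefined <- FALSE
  value <- NA_real_
  if (dq == 0) {
    undefined <- TRUE
  } else if (dc < 0 && dq > 0) {
    dominance <- "dominant"
  } else if (dc > 0 && dq < 0) {
    dominance <- "dominated"
  } else {
    value <- dc / dq
  }
  tibble(reference = ra$strategy, comparator = rb$strategy,
         delta_cost = dc, delta_qaly = dq, icer = value,
         dominance = dominance, undefined = undefined)
}

#' Cost-effectiveness frontier with extended dominance
#'
#' Orders strategies by cost, removes strictly dominated ones (another
#' strategy costs no more and yields at least as many QALYs, one strictly),
#' then removes extendedly dominated ones (their incremental ICER exceeds
#' that of the next frontier member) until the sequence of frontier ICERs
#' is non-decreasing. Equally-effective equal-cost duplicates keep the
#' first by name order.
#'
#' @param outcomes A data frame with columns `strategy`, `mean_cost` (or
#'   `cost`) and `mean_qaly` (or `qaly`), or an `osteo_outcomes` object.
#' @return An `osteo_cea` tibble: `strategy`, `cost`, `qaly`,
#'   `on_frontier`, `dominance` (`"none"`, `"strict"`, `"extended"`) and
#'   `icer` versus the previous frontier member.
#' @export
frontier <- function(outcomes) {
  if (inherits(outcomes, "osteo_outcomes")) outcomes <- outcomes$summary
  tab <- tibble(strategy = outcomes$strategy,
                cost = outcomes$mean_cost %||% outcomes$cost,
                qaly = outcomes$mean_qaly %||% outcomes$qaly)
  if (nrow(tab) < 2L) abort("need at least 2 outcomes",
                            class = "osteo_input_error")
  tab <- arrange(tab, .data$cost, desc(.data$qaly), .data$strategy)
  n <- nrow(tab)
  dominance <- rep("none", n)
  # strict dominance (incl. exact duplicates: later one is dominated)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- (tab$cost[j] < tab$cost[i] && tab$qaly[j] >= tab$qaly[i]) ||
        (tab$cost[j] <= tab$cost[i] && tab$qaly[j] > tab$qaly[i]) ||
        (tab$cost[j] == tab$cost[i] && tab$qaly[j] == tab$qaly[i] && j < i)
      if (better && dominance[j] == "none") {
        dominance[i] <- "strict"
        break
      }
    }
  }
  # extended dominance on the survivors
  repeat {
    idx <- which(dominance == "none")
    if (length(idx) < 3L) break
    ic <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
    drop <- which(diff(ic) < -1e-12)
    if (!length(drop)) break
    dominance[idx[drop[1] + 1L]] <- "extended"
  }
  idx <- which(dominance == "none")
  icers <- rep(NA_real_, n)
  if (length(idx) > 1L) {
    icers[idx[-1]] <- diff(tab$cost[idx]) / diff(tab$qaly[idx])
  }
  out <- mutate(tab, on_frontier = dominance == "none",
                dominance = dominance, icer = icers)
  class(out) <- c("osteo_cea", class(out))
  out
}

#' Preferred strategy on the frontier at a willingness-to-pay threshold
#'
#' Walks up the frontier and keeps the most effective strategy whose
#' incremental ICER does not exceed `wtp` (equivalently, the strategy with
#' the highest net monetary benefit among frontier members).
#'
#' @param cea An `osteo_cea` object from [frontier()].
#' @param wtp Willingness-to-pay threshold, $/QALY.
#' @return The chosen strategy name.
#' @export
frontier_choice <- function(cea, wtp) {
  fr <- cea[cea$on_frontier, ]
  ok <- is.na(fr$icer) | fr$icer <= wtp
  keep <- fr$strategy[ok & cumsum(!ok) == 0]
  tail(keep, 1L)
}

#' Net monetary benefit
#'
#' `NMB = qaly * wtp - cost` per strategy.
#'
#' @param outcomes Outcome summary data frame or `osteo_outcomes`.
#' @param wtp Willingness-to-pay, $/QALY.
#' @return Input tibble with an `nmb` column, sorted descending.
#' @export
net_monetary_benefit <- function(outcomes, wtp) {
  if (inherits(outcomes, "osteo_outcomes")) outcomes <- outcomes$summary
  tab <- tibble(strategy = outcomes$strategy,
                cost = outcomes$mean_cost %||% outcomes$cost,
                qaly = outcomes$mean_qaly %||% outcomes$qaly)
  arrange(mutate(tab, nmb = .data$qaly * wtp - .data$cost), desc(.data$nmb))
}

default_wtp_grid <- function(params) {
  sort(unique(c(seq(0, 80000, by = 80), params$wtp, params$wtp_secondary)))
}

#' Probabilistic sensitivity analysis and acceptability curves
#'
#' Second-order Monte Carlo: each outer iteration draws one parameter set
#' from the PSA distributions ([sample_psa()]) and runs a reduced inner
#' first-order cohort for every strategy under common random numbers. For
#' each willingness-to-pay value on the grid, the cost-effectiveness
#' acceptability curve (CEAC) reports the fraction of outer draws in which
#' each strategy has the highest net monetary benefit.
#'
#' @param params An [osteo_params] object.
#' @param strategies An `osteo_strategy` tibble.
#' @param n_outer Number of outer (parameter) draws.
#' @param n_inner Patients per inner first-order run.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid; defaults to $0-80 000 in $80
#'   steps plus the configured thresholds.
#' @param horizon Passed to [run_strategies()].
#' @return An `osteo_ceac` object: `ceac` tibble (`wtp`, `strategy`,
#'   `probability`) and the per-draw `draws` tibble.
#' @export
psa <- function(params, strategies = builtin_strategies(), n_outer = 1000,
                n_inner = 10000, seed = 1, wtp_grid = NULL,
                horizon = "lifetime") {
  stopifnot(n_outer >= 1)
  if (is.null(wtp_grid)) wtp_grid <- default_wtp_grid(params)
  S <- nrow(strategies)
  costs <- matrix(NA_real_, n_outer, S)
  qalys <- matrix(NA_real_, n_outer, S)
  for (i in seq_len(n_outer)) {
    p_i <- sample_psa(params, seed = seed + 10000L + i)
    res <- run_strategies(p_i, strategies, n = n_inner, seed = seed,
                          horizon = horizon)
    costs[i, ] <- res$summary$mean_cost
    qalys[i, ] <- res$summary$mean_qaly
  }
  colnames(costs) <- colnames(qalys) <- strategies$name
  prob <- vapply(wtp_grid, function(w) {
    win <- max.col(qalys * w - costs, ties.method = "first")
    tabulate(win, nbins = S) / n_outer
  }, numeric(S))
  ceac <- tibble(wtp = rep(wtp_grid, each = S),
                 strategy = rep(strategies$name, length(wtp_grid)),
                 probability = as.numeric(prob))
  draws <- bind_rows(lapply(seq_len(S), function(s) {
    tibble(draw = seq_len(n_outer), strategy = strategies$name[s],
           cost = costs[, s], qaly = qalys[, s])
  }))
  out <- list(ceac = ceac, draws = draws, n_outer = n_outer,
              n_inner = n_inner, wtp_grid = wtp_grid)
  class(out) <- "osteo_ceac"
  out
}

#' @export
print.osteo_ceac <- function(x, ...) {
  cat(sprintf("<osteo_ceac> %d outer draws x %d inner patients, %d WTP points\n",
              x$n_outer, x$n_inner, length(x$wtp_grid)))
  invisible(x)
}

#' Default one-way sensitivity ranges
#'
#' Deterministic-sensitivity ranges for every PSA-flagged parameter that
#' carries a (low, high) range, plus the discount rate (0 to 8%/year).
#'
#' @param params An [osteo_params] object.
#' @return A tibble with `parameter`, `path` (list column), `low`, `high`.
#' @export
default_dsa_ranges <- function(params) {
  rows <- keep(params$psa, ~ !is.null(.x$low) && !is.null(.x$high))
  out <- bind_rows(lapply(rows, function(e) {
    tibble(parameter = paste(unlist(e$path), collapse = "$"),
           path = list(unlist(e$path)), low = e$low, high = e$high)
  }))
  bind_rows(out, tibble(parameter = "discount_rate",
                        path = list("discount_rate"), low = 0, high = 0.08))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-computes the ICER of `comparator` versus `reference` with each
#' parameter set to its lower and upper bound in turn, under common random
#' numbers, and sorts parameters by the width of the resulting ICER
#' interval.
#'
#' @param params An [osteo_params] object.
#' @param reference,comparator One-row `osteo_strategy` specs.
#' @param ranges Ranges tibble, see [default_dsa_ranges()].
#' @param n Patients per run.
#' @param seed Integer seed.
#' @param horizon Simulation horizon.
#' @return An `osteo_tornado` tibble: `parameter`, `low`, `high`,
#'   `icer_low`, `icer_high`, `spread`, plus the base-case ICER as an
#'   attribute, sorted by decreasing `spread`.
#' @export
tornado <- function(params, reference, comparator,
                    ranges = default_dsa_ranges(params), n = 10000,
                    seed = 1, horizon = "lifetime") {
  pair <- bind_rows(reference, comparator)
  run_icer <- function(p) {
    res <- run_strategies(p, pair, n = n, seed = seed, horizon = horizon)
    icer(res$outcomes[[1]], res$outcomes[[2]])$icer
  }
  base_icer <- run_icer(params)
  rows <- lapply(seq_len(nrow(ranges)), function(k) {
    path <- ranges$path[[k]]
    p_lo <- osteo_params(param_set(unclass(params), path, ranges$low[k]))
    p_hi <- osteo_params(param_set(unclass(params), path, ranges$high[k]))
    tibble(parameter = ranges$parameter[k],
           low = ranges$low[k], high = ranges$high[k],
           icer_low = run_icer(p_lo), icer_high = run_icer(p_hi))
  })
  out <- bind_rows(rows) |>
    mutate(spread = abs(.data$icer_high - .data$icer_low)) |>
    arrange(desc(.data$spread))
  attr(out, "base_icer") <- base_icer
  class(out) <- c("osteo_tornado", class(out))
  out
}
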
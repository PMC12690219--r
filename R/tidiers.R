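#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a parametric survival fit
#'
#' @param x An `osteo_survfit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy osteo_survfit
#' @export
tidy.osteo_survfit <- function(x, ...) {
  tibble(term = names(x$params), estimate = unname(x$params))
}

#' @rdname tidy.osteo_survfit
#' @return For `glance()`: one row with `distribution`, `aic`, `loglik`,
#'   `n`.
#' @method glance osteo_survfit
#' @export
glance.osteo_survfit <- function(x, ...) {
  tibble(distribution = x$distribution, aic = x$aic, loglik = x$loglik,
         n = x$n_fit)
}

#' Tidy simulation outcomes
#'
#' @param x An `osteo_outcomes` object from [run_strategies()].
#' @param ... Unused.
#' @return The per-strategy summary tibble.
#' @method tidy osteo_outcomes
#' @export
tidy.osteo_outcomes <- function(x, ...) x$summary

#' @rdname tidy.osteo_outcomes
#' @method glance osteo_outcomes
#' @export
glance.osteo_outcomes <- function(x, ...) {
  tibble(n_strategies = nrow(x$summary), n = x$n, seed = x$seed,
         horizon = paste(x$horizon, collapse = ""))
}

#' Tidy a cost-effectiveness frontier
#'
#' @param x An `osteo_cea` from [frontier()].
#' @param ... Unused.
#' @return The frontier tibble (strategy, cost, qaly, dominance, icer).
#' @method tidy osteo_cea
#' @export
tidy.osteo_cea <- function(x, ...) as_tibble(x)

#' Tidy an acceptability-curve analysis
#'
#' @param x An `osteo_ceac` from [psa()].
#' @param ... Unused.
#' @return The CEAC tibble (`wtp`, `strategy`, `probability`).
#' @method tidy osteo_ceac
#' @export
tidy.osteo_ceac <- function(x, ...) x$ceac

#' @rdname tidy.osteo_ceac
#' @method glance osteo_ceac
#' @export
glance.osteo_ceac <- function(x, ...) {
  tibble(n_outer = x$n_outer, n_inner = x$n_inner,
         n_wtp = length(x$wtp_grid))
}
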
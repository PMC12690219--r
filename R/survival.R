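#' Digitized Kaplan-Meier curve
#'
#' Container for a digitized Kaplan-Meier (KM) curve together with its
#' numbers-at-risk table, the input to pseudo-individual-patient-data
#' reconstruction ([reconstruct_ipd()]).
#'
#' @param times Numeric vector of time points (years), non-decreasing,
#'   starting at or after 0.
#' @param survival Survival probabilities at `times`: non-increasing,
#'   starting at or below 1.
#' @param risk_table Data frame with columns `time` and `n_risk`
#'   (numbers at risk, non-increasing).
#' @param total_events Optional total number of events over the whole
#'   follow-up, used to pin down the last risk interval.
#' @return An object of class `km_curve`.
#' @export
km_curve <- function(times, survival, risk_table, total_events = NULL) {
  stopifnot(is.numeric(times), is.numeric(survival),
            length(times) == length(survival))
  if (any(times < 0)) abort("KM times must be non-negative")
  if (is.unsorted(times)) abort("KM times must be non-decreasing")
  if (survival[1] > 1 + 1e-12) abort("KM survival must start at or below 1")
  if (any(diff(survival) > 1e-12)) abort("KM survival must be non-increasing")
  risk_table <- as_tibble(risk_table)
  stopifnot(all(c("time", "n_risk") %in% names(risk_table)))
  if (any(diff(risk_table$n_risk) > 0)) {
    abort("numbers at risk must be non-increasing", class = "osteo_km_error")
  }
  if (is.unsorted(risk_table$time)) {
    abort("risk-table times must be non-decreasing", class = "osteo_km_error")
  }
  structure(list(times = as.numeric(times), survival = as.numeric(survival),
                 risk_table = risk_table,
                 total_events = total_events),
            class = "km_curve")
}

#' Read a digitized KM curve from delimited text files
#'
#' The curve file needs columns `time` and `survival`; the risk-table file
#' columns `time` and `n_risk`. Any delimiter `read.delim`-style
#' auto-detection handles (comma or whitespace/tab) works.
#'
#' @param file Path to the digitized curve file.
#' @param risk_file Path to the numbers-at-risk file.
#' @param total_events Optional total event count.
#' @return A [km_curve].
#' @export
read_km <- function(file, risk_file, total_events = NULL) {
  read_any <- function(path) {
    first <- readLines(path, n = 1L)
    if (grepl(",", first)) utils::read.csv(path) else
      utils::read.table(path, header = TRUE)
  }
  curve <- read_any(file)
  risk <- read_any(risk_file)
  stopifnot(all(c("time", "survival") %in% names(curve)),
            all(c("time", "n_risk") %in% names(risk)))
  km_curve(curve$time, curve$survival, risk, total_events = total_events)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d digitized points over [%.2f, %.2f] y, %d risk-table rows\n",
              length(x$times), min(x$times), max(x$times),
              nrow(x$risk_table)))
  invisible(x)
}

#' Reconstruct pseudo-individual-patient data from a digitized KM curve
#'
#' Interval-wise allocation of event and censoring counts consistent with
#' the published numbers at risk (the Guyot-type reconstruction used to
#' recover individual patient data from published survival figures). Within
#' each risk-table interval the censoring count is adjusted iteratively so
#' the implied number at risk at the next interval boundary matches the
#' published value; events are then recovered click by click from the KM
#' product-limit relation. Censoring in the final interval is extrapolated
#' from the earlier censoring rate unless `total_events` pins it down.
#'
#' @param km A [km_curve]. The risk table needs at least two entries.
#' @return A tibble of class `pseudo_ipd` with columns `time` (years) and
#'   `event` (1 = event, 0 = censored); its re-estimated KM curve matches
#'   the input at every digitized time within 0.02 in well-posed cases.
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "km_curve"))
  if (nrow(km$risk_table) < 2L) {
    abort("risk table must have at least 2 entries", class = "osteo_km_error")
  }
  t_s <- km$times
  s <- pmin(km$survival, 1)
  trisk <- km$risk_table$time
  nrisk <- round(km$risk_table$n_risk)
  # drop risk-table entries beyond the digitized range
  keep <- trisk <= max(t_s) + 1e-9
  trisk <- trisk[keep]; nrisk <- nrisk[keep]
  n_int <- length(nrisk)
  n_t <- length(t_s)
  lower <- vapply(trisk, function(tt) which(t_s >= tt - 1e-9)[1], integer(1))
  if (anyNA(lower)) abort("risk-table times outside the digitized grid")
  upper <- c(lower[-1] - 1L, n_t)

  n_censor <- integer(n_int)
  n_hat <- rep(NA_real_, n_t + 1L)
  cen <- integer(n_t)
  d <- integer(n_t)
  km_hat <- rep(1, n_t)
  last_i <- rep(1L, n_int)
  n_hat[lower[1]] <- nrisk[1]

  click_events <- function(k, last) {
    # events implied by the product-limit relation at click k
    if (km_hat[last] <= 0 || n_hat[k] <= 0) return(0)
    dk <- round(n_hat[k] * (1 - s[k] / km_hat[last]))
    max(min(dk, n_hat[k]), 0)
  }

  run_interval <- function(i, last0) {
    # forward pass over clicks in interval i; returns updated vectors
    last <- last0
    n_hat[lower[i]] <<- nrisk[i]
    for (k in seq(lower[i], upper[i])) {
      if (i == 1L && k == lower[i]) {
        d[k] <<- 0L
        km_hat[k] <<- 1
      } else {
        dk <- click_events(k, last)
        d[k] <<- dk
        km_hat[k] <<- if (n_hat[k] > 0) km_hat[last] * (1 - dk / n_hat[k]) else 0
      }
      n_hat[k + 1L] <<- n_hat[k] - d[k] - cen[k]
      if (d[k] != 0L) last <- k
    }
    last
  }

  if (n_int > 1L) {
    for (i in seq_len(n_int - 1L)) {
      s_lo <- max(s[lower[i]], .Machine$double.eps)
      n_censor[i] <- round(nrisk[i] * s[lower[i + 1L]] / s_lo - nrisk[i + 1L])
      iter <- 0L
      repeat {
        iter <- iter + 1L
        if (n_censor[i] <= 0L) {
          cen[lower[i]:upper[i]] <- 0L
          n_censor[i] <- 0L
        } else {
          cen_t <- t_s[lower[i]] + seq_len(n_censor[i]) *
            (t_s[lower[i + 1L]] - t_s[lower[i]]) / (n_censor[i] + 1L)
          cen[lower[i]:upper[i]] <-
            tabulate(findInterval(cen_t, t_s[lower[i]:lower[i + 1L]],
                                  rightmost.closed = FALSE),
                     nbins = upper[i] - lower[i] + 1L)
        }
        last_i[i + 1L] <- run_interval(i, last_i[i])
        # digitized survival at a click already includes any events at that
        # time, so the published at-risk count is compared net of the
        # boundary click's events
        d_bound <- click_events(lower[i + 1L], last_i[i + 1L])
        at_risk_next <- n_hat[lower[i + 1L]] - d_bound
        gap <- at_risk_next - nrisk[i + 1L]
        done <- !(gap > 0L || (gap < 0L && n_censor[i] > 0L))
        if (done || iter > 200L) break
        n_censor[i] <- n_censor[i] + gap
      }
      d_bound <- click_events(lower[i + 1L], last_i[i + 1L])
      if (n_hat[lower[i + 1L]] - d_bound < nrisk[i + 1L]) {
        nrisk[i + 1L] <- n_hat[lower[i + 1L]] - d_bound
      }
      nrisk[i + 1L] <- nrisk[i + 1L] + d_bound
    }
  }

  # last interval: extrapolate the earlier censoring rate, or honour
  # total_events when supplied
  i <- n_int
  if (upper[i] >= lower[i]) {
    set_last_cen <- function(nc) {
      if (nc > 0L) {
        cen_t <- t_s[lower[i]] + seq_len(nc) *
          (t_s[upper[i]] - t_s[lower[i]] + 1e-9) / (nc + 1L)
        cen[lower[i]:upper[i]] <<-
          tabulate(findInterval(cen_t, t_s[lower[i]:upper[i]],
                                rightmost.closed = TRUE),
                   nbins = upper[i] - lower[i] + 1L)
      } else cen[lower[i]:upper[i]] <<- 0L
    }
    if (!is.null(km$total_events)) {
      target <- km$total_events
      best <- list(nc = 0L, gap = Inf)
      for (nc in 0:max(nrisk[i], 0)) {
        set_last_cen(nc)
        run_interval(i, last_i[i])
        tot <- sum(d[1:upper[i]])
        if (abs(tot - target) < best$gap) {
          best <- list(nc = nc, gap = abs(tot - target))
        }
        if (tot <= target) break
      }
      n_censor[i] <- best$nc
    } else {
      span_prev <- t_s[upper[max(i - 1L, 1L)]] - t_s[lower[1L]]
      rate <- if (i > 1L && span_prev > 0) {
        sum(n_censor[seq_len(i - 1L)]) / span_prev
      } else 0
      n_censor[i] <- max(min(round(rate * (t_s[upper[i]] - t_s[lower[i]])),
                             nrisk[i]), 0L)
    }
    set_last_cen(n_censor[i])
    run_interval(i, last_i[i])
  }

  # anyone still at risk after the last click is censored administratively.
  # The digitized value at a click covers events since the previous click,
  # so reconstructed event times sit at the interval midpoint to avoid a
  # systematic half-step shift.
  n_left <- n_hat[n_t + 1L]
  mid <- t_s - c(0, diff(t_s)) / 2
  times <- c(rep(mid, d), rep(t_s, cen),
             rep(max(t_s), max(n_left, 0)))
  event <- c(rep(1L, sum(d)), rep(0L, sum(cen)),
             rep(0L, max(n_left, 0)))
  out <- tibble(time = times, event = event) |> arrange(.data$time)
  class(out) <- c("pseudo_ipd", class(out))
  out
}

# canonical distribution registry -------------------------------------------

surv_param_names <- function(distribution) {
  switch(distribution,
    exponential = "rate",
    weibull = c("shape", "scale"),
    gompertz = c("shape", "rate"),
    loglogistic = c("shape", "scale"),
    lognormal = c("meanlog", "sdlog"),
    generalized_gamma = c("mu", "sigma", "Q"))
}

# Validation hook used by the parameter schema for stored survival fits.
check_fit_params <- function(distribution, params, field) {
  if (!distribution %in% surv_distributions()) {
    fail_param(field, sprintf("unknown distribution '%s'", distribution))
  }
  needed <- surv_param_names(distribution)
  missing_p <- setdiff(needed, names(params))
  if (length(missing_p)) {
    fail_param(field, paste("missing parameter(s):",
                            paste(missing_p, collapse = ", ")))
  }
  scale_p <- intersect(names(params), c("sdlog", "sigma", "scale"))
  if (length(scale_p) && any(params[scale_p] <= 0)) {
    fail_param(field, "scale parameters must be positive", params[scale_p])
  }
  invisible(TRUE)
}

surv_distributions <- function() {
  c("exponential", "weibull", "gompertz", "loglogistic", "lognormal",
    "generalized_gamma")
}

flexsurv_dist_name <- function(distribution) {
  switch(distribution,
    exponential = "exp",
    weibull = "weibull",
    gompertz = "gompertz",
    loglogistic = "llogis",
    lognormal = "lnorm",
    generalized_gamma = "gengamma",
    abort(sprintf("unknown survival distribution '%s'", distribution),
          class = "osteo_dist_error")
  )
}

surv_n_params <- function(distribution) {
  switch(distribution,
    exponential = 1L, weibull = 2L, gompertz = 2L, loglogistic = 2L,
    lognormal = 2L, generalized_gamma = 3L)
}

#' Construct a parametric survival fit by hand
#'
#' Used for fits supplied in a parameter file rather than estimated from
#' data. The generalized gamma uses the (mu, sigma, Q) parameterization in
#' which `Q = 1` recovers a Weibull with shape `1/sigma` and scale
#' `exp(mu)`, and `Q = 0` the log-normal.
#'
#' @param distribution One of `"exponential"` (rate), `"weibull"` (shape,
#'   scale), `"gompertz"` (shape, rate), `"loglogistic"` (shape, scale),
#'   `"lognormal"` (meanlog, sdlog), `"generalized_gamma"` (mu, sigma, Q).
#' @param params Named numeric vector of natural-scale parameters.
#' @param aic,loglik,n_fit Optional fit metadata.
#' @return An object of class `osteo_survfit`.
#' @export
survival_fit <- function(distribution, params, aic = NA_real_,
                         loglik = NA_real_, n_fit = NA_integer_) {
  distribution <- match.arg(distribution, surv_distributions())
  params <- unlist(params)
  scale_pars <- c("sdlog", "sigma", "scale", "rate")
  pos <- intersect(names(params), c("sdlog", "sigma"))
  if (length(pos) && any(params[pos] <= 0)) {
    abort("scale parameters must be strictly positive",
          class = "osteo_dist_error")
  }
  structure(list(distribution = distribution, params = params,
                 aic = aic, loglik = loglik, n_fit = n_fit),
            class = "osteo_survfit")
}

#' @export
print.osteo_survfit <- function(x, ...) {
  cat(sprintf("<osteo_survfit> %s(%s)%s\n", x$distribution,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = ", "),
              if (is.finite(x$aic)) sprintf(", AIC %.1f", x$aic) else ""))
  invisible(x)
}

#' Fit a parametric survival distribution to pseudo-IPD
#'
#' Maximum-likelihood fit via [flexsurv::flexsurvreg()] of one of the six
#' candidate families (exponential, Weibull, Gompertz, log-logistic,
#' log-normal, generalized gamma).
#'
#' @param ipd A data frame with columns `time` and `event` (at least 10
#'   records including at least one event).
#' @param distribution Distribution name, see [survival_fit()].
#' @return An `osteo_survfit` with ML parameters, `aic = 2k - 2 logLik`,
#'   and the fitting sample size.
#' @export
fit_parametric <- function(ipd, distribution) {
  distribution <- match.arg(distribution, surv_distributions())
  stopifnot(all(c("time", "event") %in% names(ipd)))
  if (nrow(ipd) < 10L) {
    abort("need at least 10 records to fit", class = "osteo_fit_error")
  }
  if (sum(ipd$event) < 1L) {
    abort("cannot fit a survival model with no events",
          class = "osteo_fit_error")
  }
  dat <- data.frame(time = pmax(ipd$time, 1e-9), event = ipd$event)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                          dist = flexsurv_dist_name(distribution)),
    error = function(e) {
      abort(sprintf("survival fit did not converge for '%s': %s",
                    distribution, conditionMessage(e)),
            class = "osteo_convergence_error")
    })
  params <- fit$res[, "est"]
  survival_fit(distribution, params, aic = stats::AIC(fit),
               loglik = as.numeric(stats::logLik(fit)), n_fit = nrow(dat))
}

#' Fit all six candidate distributions
#'
#' @param ipd Pseudo-IPD data frame (`time`, `event`).
#' @return Named list of `osteo_survfit` objects; families that fail to
#'   converge are dropped with a warning.
#' @export
fit_all_parametric <- function(ipd) {
  fits <- list()
  for (d in surv_distributions()) {
    f <- tryCatch(fit_parametric(ipd, d), error = function(e) {
      warn(sprintf("dropping '%s': %s", d, conditionMessage(e)))
      NULL
    })
    if (!is.null(f)) fits[[d]] <- f
  }
  fits
}

#' Select the best-fitting distribution by AIC
#'
#' Minimum AIC wins; ties are broken by fewer parameters, then by the fixed
#' registry order (exponential, Weibull, Gompertz, log-logistic, log-normal,
#' generalized gamma).
#'
#' @param fits Non-empty list of `osteo_survfit` objects.
#' @return The selected `osteo_survfit`.
#' @export
select_best <- function(fits) {
  if (length(fits) == 0L) {
    abort("no fits to select from", class = "osteo_fit_error")
  }
  aics <- map_dbl(fits, "aic")
  npar <- map_dbl(fits, ~ surv_n_params(.x$distribution))
  ord <- match(map_chr(fits, "distribution"), surv_distributions())
  fits[[order(aics, npar, ord)[1]]]
}

#' Evaluate a fitted survival function
#'
#' `S(t)` for the stored distribution; `S(0) = 1` and `S` is non-increasing
#' with values in \[0, 1\]. For the log-normal,
#' `S(t) = 1 - pnorm((log(t) - meanlog) / sdlog)`.
#'
#' @param fit An `osteo_survfit`.
#' @param t Time(s) in years, non-negative.
#' @return Survival probabilities, vectorized over `t`.
#' @export
survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "osteo_survfit"))
  if (any(t < 0)) abort("t must be non-negative", class = "osteo_domain_error")
  p <- fit$params
  switch(fit$distribution,
    exponential = pexp(t, rate = p[["rate"]], lower.tail = FALSE),
    weibull = pweibull(t, shape = p[["shape"]], scale = p[["scale"]],
                       lower.tail = FALSE),
    gompertz = flexsurv::pgompertz(t, shape = p[["shape"]], rate = p[["rate"]],
                                   lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p[["shape"]],
                                    scale = p[["scale"]], lower.tail = FALSE),
    lognormal = plnorm(t, meanlog = p[["meanlog"]], sdlog = p[["sdlog"]],
                       lower.tail = FALSE),
    generalized_gamma = flexsurv::pgengamma(t, mu = p[["mu"]],
                                            sigma = p[["sigma"]], Q = p[["Q"]],
                                            lower.tail = FALSE)
  )
}

#' Per-cycle transition probability from a survival fit
#'
#' The conditional probability for cycle `t` derived from the survival
#' ratio `S(t) / S(t-1)`: with `type = "stay"` the probability of remaining
#' in the state through cycle `t`, with `type = "leave"` (the default, what
#' the simulation engine consumes) its complement `1 - S(t)/S(t-1)`.
#'
#' @param fit An `osteo_survfit`.
#' @param cycle Integer cycle number(s), `>= 1`.
#' @param type `"leave"` or `"stay"`.
#' @return Probabilities in \[0, 1\], vectorized over `cycle`.
#' @export
transition_probability <- function(fit, cycle, type = c("leave", "stay")) {
  type <- match.arg(type)
  if (any(cycle < 1)) {
    abort("cycle must be >= 1", class = "osteo_domain_error")
  }
  s_prev <- survival_at(fit, cycle - 1)
  if (any(s_prev <= 0)) {
    abort("S(cycle - 1) = 0: state already absorbed",
          class = "osteo_absorbed_error")
  }
  stay <- clamp01(survival_at(fit, cycle) / s_prev)
  if (type == "stay") stay else 1 - stay
}
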
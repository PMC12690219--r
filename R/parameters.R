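#' Model parameter sets
#'
#' An `osteo_params` object holds every input of the fracture-prevention
#' cost-effectiveness model: parametric survival fits for the breast-cancer
#' transitions, age-indexed fracture incidence curves and their
#' bone-mineral-density (BMD) risk gradients, BMD trajectory parameters and
#' the T-score/Z-score reference, treatment effects with residual (offset)
#' periods, adherence, utilities, costs (healthcare and societal), the
#' discount rate and willingness-to-pay threshold, and the probabilistic
#' sensitivity analysis (PSA) distributions.
#'
#' Age-indexed inputs are stored as banded tables (columns `age` + values)
#' and looked up as step functions of integer age, matching the one-year
#' cycle length of the simulation.
#'
#' @param x A named list with the documented fields (see
#'   [make_default_params()] for a complete example).
#' @return `osteo_params(x)` validates `x` and returns it classed as
#'   `osteo_params`.
#' @seealso [load_parameters()], [write_parameters()], [sample_psa()]
#' @export
osteo_params <- function(x) {
  x <- restore_param_tables(x)
  validate_params(x)
  structure(x, class = "osteo_params")
}

# Top-level schema: required field -> predicate description.
param_schema <- function() {
  c("discount_rate", "wtp", "wtp_secondary", "start_age", "max_age",
    "ai_years", "cancer_transition_fits", "fracture_rate_curves",
    "fracture_rate_scale", "gradient_rr_per_sd", "rr_subsequent_fracture",
    "p_bedridden_after_hip", "hip_fracture_mortality_hr",
    "background_mortality", "bmd_baseline", "bmd_loss_on_ai",
    "bmd_loss_natural", "zscore_reference", "young_adult_age",
    "treatment_rr", "treatment_duration", "residual_duration",
    "adherence", "risk_modifiers", "utilities", "costs", "psa", "meta")
}

cancer_transitions <- function() {
  c("dfs_to_lrs", "dfs_to_crs", "lrs_to_dm", "crs_to_dm", "dm_to_death")
}

fracture_sites <- function() c("hip", "vertebral", "other")

model_drugs <- function() c("alendronate", "denosumab", "zoledronate")

# Tables arrive from YAML as lists of records; restore them to data frames.
restore_param_tables <- function(x) {
  tab_fields <- c("hip_fracture_mortality_hr", "background_mortality",
                  "bmd_baseline", "bmd_loss_natural", "zscore_reference")
  for (f in tab_fields) {
    if (!is.null(x[[f]]) && !is.data.frame(x[[f]])) {
      x[[f]] <- bind_rows(x[[f]])
    }
  }
  if (!is.null(x$utilities$baseline_by_age) &&
      !is.data.frame(x$utilities$baseline_by_age)) {
    x$utilities$baseline_by_age <- bind_rows(x$utilities$baseline_by_age)
  }
  x
}

fail_param <- function(field, msg, value = NULL) {
  detail <- if (!is.null(value)) {
    sprintf(" (got %s)", paste(format(value), collapse = ", "))
  } else ""
  abort(sprintf("invalid parameter '%s': %s%s", field, msg, detail),
        class = "osteo_param_error")
}

check_prob <- function(x, field) {
  if (!is_scalar_number(x) || x < 0 || x > 1) {
    fail_param(field, "must be a probability in [0, 1]", x)
  }
}

check_nonneg <- function(x, field) {
  if (!all(is.finite(unlist(x))) || any(unlist(x) < 0)) {
    fail_param(field, "must be non-negative and finite", unlist(x))
  }
}

check_pos <- function(x, field) {
  if (!all(is.finite(unlist(x))) || any(unlist(x) <= 0)) {
    fail_param(field, "must be strictly positive", unlist(x))
  }
}

check_age_table <- function(tab, field, start_age, cols) {
  if (!is.data.frame(tab) || !"age" %in% names(tab) || nrow(tab) < 1L) {
    fail_param(field, "must be a data frame with an 'age' column")
  }
  missing_cols <- setdiff(cols, names(tab))
  if (length(missing_cols)) {
    fail_param(field, paste("missing column(s):",
                            paste(missing_cols, collapse = ", ")))
  }
  if (is.unsorted(tab$age, strictly = TRUE)) {
    fail_param(field, "'age' must be strictly increasing")
  }
  if (min(tab$age) > start_age) {
    fail_param(field,
               sprintf("age coverage must start at or below %d", start_age),
               min(tab$age))
  }
}

check_site_map <- function(x, field, positive = TRUE) {
  missing_sites <- setdiff(fracture_sites(), names(x))
  if (length(missing_sites)) {
    fail_param(field, paste("missing site(s):",
                            paste(missing_sites, collapse = ", ")))
  }
  if (positive) check_pos(x, field) else check_nonneg(x, field)
}

#' Validate a parameter set
#'
#' Checks the full schema: required fields present, unknown fields rejected,
#' probabilities in \[0, 1\], rates and costs non-negative, relative risks
#' positive, utilities in \[-1, 1\], age tables covering the simulated age
#' range, and PSA distributions whose support respects each parameter's
#' domain. Errors name the offending field and value.
#'
#' @param x A parameter list.
#' @return `x`, invisibly, if valid.
#' @export
validate_params <- function(x) {
  required <- param_schema()
  missing_f <- setdiff(required, names(x))
  if (length(missing_f)) {
    abort(sprintf("parameter file is missing required field(s): %s",
                  paste(missing_f, collapse = ", ")),
          class = "osteo_schema_error")
  }
  unknown <- setdiff(names(x), required)
  if (length(unknown)) {
    abort(sprintf("unknown parameter field(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "osteo_schema_error")
  }

  check_prob(x$discount_rate, "discount_rate")
  check_pos(x$wtp, "wtp")
  check_pos(x$wtp_secondary, "wtp_secondary")
  if (!is_scalar_number(x$start_age) || x$start_age < 18) {
    fail_param("start_age", "must be an adult age", x$start_age)
  }
  if (!is_scalar_number(x$max_age) || x$max_age <= x$start_age) {
    fail_param("max_age", "must exceed start_age", x$max_age)
  }
  check_pos(x$ai_years, "ai_years")

  missing_tr <- setdiff(cancer_transitions(), names(x$cancer_transition_fits))
  if (length(missing_tr)) {
    fail_param("cancer_transition_fits",
               paste("missing transition(s):",
                     paste(missing_tr, collapse = ", ")))
  }
  for (tr in cancer_transitions()) {
    fit <- x$cancer_transition_fits[[tr]]
    if (is.null(fit$distribution) || is.null(fit$params)) {
      fail_param(paste0("cancer_transition_fits$", tr),
                 "must have 'distribution' and 'params'")
    }
    check_fit_params(fit$distribution, unlist(fit$params),
                     paste0("cancer_transition_fits$", tr))
  }

  for (s in fracture_sites()) {
    cf <- x$fracture_rate_curves[[s]]
    if (is.null(cf) || !all(c("a", "b") %in% names(unlist(cf)))) {
      fail_param(paste0("fracture_rate_curves$", s),
                 "must have exponential coefficients 'a' and 'b'")
    }
    check_nonneg(unlist(cf)[["a"]], paste0("fracture_rate_curves$", s, "$a"))
  }
  check_site_map(x$fracture_rate_scale, "fracture_rate_scale")
  check_site_map(x$gradient_rr_per_sd, "gradient_rr_per_sd")
  check_site_map(x$rr_subsequent_fracture, "rr_subsequent_fracture")
  check_prob(x$p_bedridden_after_hip, "p_bedridden_after_hip")

  check_age_table(x$hip_fracture_mortality_hr, "hip_fracture_mortality_hr",
                  x$start_age, "hr")
  check_pos(x$hip_fracture_mortality_hr$hr, "hip_fracture_mortality_hr$hr")
  check_age_table(x$background_mortality, "background_mortality",
                  x$start_age, "qx")
  if (any(x$background_mortality$qx < 0) ||
      any(x$background_mortality$qx > 1)) {
    fail_param("background_mortality$qx", "must be probabilities in [0, 1]")
  }
  if (max(x$background_mortality$age) < x$max_age) {
    fail_param("background_mortality",
               sprintf("must cover ages up to max_age = %d", x$max_age),
               max(x$background_mortality$age))
  }
  check_age_table(x$bmd_baseline, "bmd_baseline", x$start_age,
                  c("mean_tscore", "sd_tscore"))
  # a zero SD (degenerate baseline) is allowed for homogeneous cohorts
  check_nonneg(x$bmd_baseline$sd_tscore, "bmd_baseline$sd_tscore")
  check_nonneg(x$bmd_loss_on_ai, "bmd_loss_on_ai")
  check_age_table(x$bmd_loss_natural, "bmd_loss_natural", x$start_age, "loss")
  check_nonneg(x$bmd_loss_natural$loss, "bmd_loss_natural$loss")
  check_age_table(x$zscore_reference, "zscore_reference", x$start_age,
                  c("mean_tscore", "sd_tscore"))
  check_pos(x$zscore_reference$sd_tscore, "zscore_reference$sd_tscore")

  for (d in names(x$treatment_rr)) {
    # RRs are positive; draws marginally above 1 (parameter uncertainty)
    # are tolerated and decay toward 1 after treatment stops
    check_site_map(x$treatment_rr[[d]], paste0("treatment_rr$", d))
  }
  missing_drug <- setdiff(names(x$treatment_rr), names(x$treatment_duration))
  if (length(missing_drug)) {
    fail_param("treatment_duration",
               paste("missing drug(s):", paste(missing_drug, collapse = ", ")))
  }
  check_pos(x$treatment_duration, "treatment_duration")
  check_nonneg(x$residual_duration, "residual_duration")
  check_prob(x$adherence, "adherence")
  check_pos(x$risk_modifiers, "risk_modifiers")

  u <- x$utilities
  check_age_table(u$baseline_by_age, "utilities$baseline_by_age",
                  x$start_age, "utility")
  all_u <- c(u$baseline_by_age$utility, unlist(u$cancer_state),
             unlist(u$fracture_multiplier_first),
             unlist(u$fracture_multiplier_subsequent), u$bedridden)
  if (any(!is.finite(all_u)) || any(all_u < -1) || any(all_u > 1)) {
    fail_param("utilities", "all utility values must lie in [-1, 1]", all_u)
  }
  if (!u$fracture_decrement_form %in% c("multiplicative", "additive")) {
    fail_param("utilities$fracture_decrement_form",
               "must be 'multiplicative' or 'additive'",
               u$fracture_decrement_form)
  }

  co <- x$costs
  check_nonneg(co$drug_annual, "costs$drug_annual")
  check_nonneg(co$dxa, "costs$dxa")
  check_site_map(co$fracture_acute, "costs$fracture_acute", positive = FALSE)
  check_site_map(co$fracture_management_annual,
                 "costs$fracture_management_annual", positive = FALSE)
  check_nonneg(co$long_term_care_annual, "costs$long_term_care_annual")
  check_nonneg(co$indirect, "costs$indirect")

  for (entry in x$psa) {
    validate_psa_entry(entry, x)
  }
  invisible(x)
}

# Path-based getter/setter into the nested parameter list.
param_get <- function(params, path) {
  Reduce(function(acc, k) acc[[k]], unlist(path), init = params)
}

param_set <- function(params, path, value) {
  path <- unlist(path)
  if (length(path) == 1L) {
    params[[path]] <- value
    return(params)
  }
  params[[path[[1L]]]] <- param_set(params[[path[[1L]]]], path[-1L], value)
  params
}

validate_psa_entry <- function(entry, params) {
  path <- unlist(entry$path)
  label <- paste(path, collapse = "$")
  base <- param_get(params, path)
  if (is.null(base)) fail_param(label, "PSA entry targets an unknown parameter")
  dist <- entry$dist
  if (!dist %in% c("beta", "gamma", "lognormal", "normal", "point")) {
    fail_param(label, "unknown PSA distribution family", dist)
  }
  # Support must respect the target's domain: probabilities/utilities need a
  # [0,1] family, rates/costs a non-negative family.
  domain <- psa_domain(path)
  ok <- switch(dist,
    beta = TRUE,
    gamma = , lognormal = domain %in% c("nonneg", "positive", "real"),
    normal = domain == "real",
    point = TRUE
  )
  if (!ok) {
    fail_param(label, sprintf(
      "distribution '%s' can leave the parameter's domain ('%s')",
      dist, domain))
  }
}

# Crude domain classification by path for PSA support checks.
psa_domain <- function(path) {
  head_f <- path[[1]]
  if (head_f %in% c("p_bedridden_after_hip", "adherence")) return("unit")
  if (head_f == "utilities") return("unit")
  if (head_f %in% c("costs", "fracture_rate_scale", "bmd_loss_on_ai")) {
    return("nonneg")
  }
  if (head_f %in% c("treatment_rr", "rr_subsequent_fracture",
                    "gradient_rr_per_sd", "risk_modifiers")) {
    return("positive")
  }
  "real"
}

#' Read a parameter file
#'
#' Loads a YAML parameter file, restores the age-indexed tables, and runs
#' full schema validation. Missing required fields raise a schema error
#' naming the field; invariant violations raise a validation error naming
#' the parameter and offending value.
#'
#' @param path Path to a YAML parameter file, e.g. the packaged default
#'   `system.file("extdata", "default_params.yaml", package = "osteocea")`.
#' @return A validated [osteo_params] object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("parameter file not found: %s", path))
  }
  raw <- yaml::read_yaml(path)
  osteo_params(raw)
}

#' Write a parameter set to a YAML file
#'
#' The canonical machine-written form; `load_parameters()` of the written
#' file round-trips to an equal parameter set.
#'
#' @param params An [osteo_params] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  x <- unclass(params)
  tab_to_records <- function(tab) {
    unname(apply(tab, 1L, function(r) as.list(r), simplify = FALSE))
  }
  for (f in c("hip_fracture_mortality_hr", "background_mortality",
              "bmd_baseline", "bmd_loss_natural", "zscore_reference")) {
    x[[f]] <- tab_to_records(x[[f]])
  }
  x$utilities$baseline_by_age <- tab_to_records(x$utilities$baseline_by_age)
  writeLines(yaml::as.yaml(x, precision = 15L), path)
  invisible(path)
}

#' Draw one probabilistic-sensitivity-analysis parameter set
#'
#' Each PSA-flagged parameter is replaced by a single draw from its
#' configured distribution (beta for probabilities and utilities, gamma for
#' costs and rates, log-normal for relative risks, point mass for degenerate
#' entries). Non-flagged parameters are untouched. The draw is deterministic
#' given `seed`.
#'
#' @param params An [osteo_params] object.
#' @param seed Integer seed for the draw.
#' @return A new [osteo_params] object with sampled values.
#' @export
sample_psa <- function(params, seed) {
  stopifnot(inherits(params, "osteo_params"))
  if (length(params$psa) == 0L) return(params)
  out <- unclass(params)
  # draws happen in the fixed order of the psa list so the mapping from
  # seed to draws is stable
  set.seed(as.integer(seed))
  for (entry in params$psa) {
    path <- unlist(entry$path)
    pars <- unlist(entry$pars)
    value <- switch(entry$dist,
      point = param_get(out, path),
      beta = rbeta(1L, pars[["shape1"]], pars[["shape2"]]),
      gamma = rgamma(1L, shape = pars[["shape"]], rate = pars[["rate"]]),
      lognormal = rlnorm(1L, pars[["meanlog"]], pars[["sdlog"]]),
      normal = rnorm(1L, pars[["mean"]], pars[["sd"]]),
      fail_param(paste(path, collapse = "$"),
                 "unknown PSA distribution", entry$dist)
    )
    out <- param_set(out, path, value)
  }
  osteo_params(out)
}

#' @export
print.osteo_params <- function(x, ...) {
  cat("<osteo_params>\n")
  cat(sprintf("  start age %d, max age %d, AI therapy %g y\n",
              x$start_age, x$max_age, x$ai_years))
  cat(sprintf("  discount rate %.1f%%/y, WTP $%s/QALY\n",
              100 * x$discount_rate, format(x$wtp, big.mark = " ")))
  cat(sprintf("  drugs: %s\n", paste(names(x$treatment_rr), collapse = ", ")))
  cat(sprintf("  %d PSA-flagged parameters\n", length(x$psa)))
  invisible(x)
}
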
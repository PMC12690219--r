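#' @keywords internal
"_PACKAGE"

#' @import dplyr
#' @import tibble
#' @importFrom rlang %||% abort warn .data
#' @importFrom purrr map map_dbl map_chr map_lgl pluck imap keep
#' @importFrom stats approx rbeta rgamma rlnorm rnorm runif setNames
#'   qnorm pnorm plnorm pweibull pexp quantile sd var optimise
#' @importFrom utils head tail modifyList
NULL

# Step-function lookup into an age-indexed table (carry last band forward,
# carry first band backward). `table` has an `age` column plus value columns.
age_lookup <- function(table, age, col) {
  if (!col %in% names(table)) {
    abort(sprintf("column '%s' not found in age-indexed table", col))
  }
  tab <- table[order(table$age), , drop = FALSE]
  if (nrow(tab) == 1L) return(rep(tab[[col]], length(age)))
  approx(tab$age, tab[[col]], xout = age, method = "constant",
         rule = 2, f = 0)$y
}

# Moment-matched beta hyperparameters for a mean in (0,1).
beta_from_mean_sd <- function(mean, sd) {
  stopifnot(mean > 0, mean < 1)
  v <- min(sd^2, 0.95 * mean * (1 - mean))
  k <- mean * (1 - mean) / v - 1
  c(shape1 = mean * k, shape2 = (1 - mean) * k)
}

# Moment-matched gamma hyperparameters for a positive mean.
gamma_from_mean_sd <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  c(shape = (mean / sd)^2, rate = mean / sd^2)
}

# Log-normal hyperparameters with median at the point estimate and sdlog
# chosen so that (low, high) is an approximate 95% interval.
lnorm_from_pe_range <- function(pe, low, high) {
  stopifnot(pe > 0, low > 0, high > low)
  c(meanlog = log(pe), sdlog = (log(high) - log(low)) / (2 * 1.959964))
}

# Discount factor for flows occurring in cycle t (cycle 0 undiscounted).
discount_factor <- function(cycle, rate) 1 / (1 + rate)^cycle

clamp01 <- function(x) pmin(pmax(x, 0), 1)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
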
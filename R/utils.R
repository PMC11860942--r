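#' @importFrom rlang %||% .data
#' @importFrom stats lm coef resid residuals qchisq pnorm pt cor sd median
#'   setNames rexp rnorm rpois runif rlnorm mahalanobis cov aggregate complete.cases
#' @importFrom utils combn head tail
NULL

# internal: abort with a penfeedr-classed condition
pf_abort <- function(msg, class = "penfeedr_error") {
  rlang::abort(msg, class = class)
}

pf_assert <- function(cond, msg, class = "penfeedr_error") {
  if (!isTRUE(cond)) pf_abort(msg, class)
}

# minutes between two POSIXct vectors
mins_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "mins"))
}

secs_between <- function(from, to) {
  as.numeric(difftime(to, from, units = "secs"))
}

# clock hour (0-23, integer) of a POSIXct in its storage timezone (UTC here)
clock_hour <- function(t) as.integer(lubridate::hour(t))

# fractional clock hour in [0, 24)
clock_hour_frac <- function(t) {
  lubridate::hour(t) + lubridate::minute(t) / 60 + lubridate::second(t) / 3600
}

# derive a 32-bit-safe child seed from a root seed and an index
child_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1009 + 7919 * as.numeric(index)) %% 2147483587) + 1L
}
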
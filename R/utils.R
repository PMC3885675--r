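`%||%` <- function(a, b) if (is.null(a)) b else a

psn_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "psn_error", "error", "condition")))
}

validation_error <- function(msg) psn_error(msg, "psn_validation_error")

calibration_error <- function(msg, residuals = NULL) {
  psn_error(msg, "psn_calibration_error", residuals = residuals)
}

check_number <- function(x, name, lower = -Inf, upper = Inf, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    validation_error(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || x > upper) {
    validation_error(sprintf("`%s` = %g is outside [%g, %g]", name, x, lower, upper))
  }
  invisible(x)
}

check_prob <- function(x, name) check_number(x, name, 0, 1)

#' Derive a reproducible child seed from a master seed
#'
#' All stochastic stages draw their seed from one master seed through this
#' map, so a single integer reproduces an entire run while keeping the
#' random streams of different stages (simulation, selection, calibration)
#' distinct. Results stay within the 32-bit integer range R requires.
#'
#' @param seed master integer seed.
#' @param offset integer stream offset (one per stage).
#' @return an integer seed.
#' @export
derive_seed <- function(seed, offset = 0) {
  check_number(seed, "seed")
  check_number(offset, "offset")
  as.integer(((abs(as.numeric(seed)) %% 2147483647) * 48271 +
                abs(as.numeric(offset)) * 9973 + 12345) %% 2147483629)
}

# Inverse-CDF draw from a normal truncated to [lower, upper]; one uniform
# per value keeps the RNG stream length independent of the bounds.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) validation_error("`sd` must be >= 0")
  if (sd == 0) {
    u <- runif(n) # keep stream advancement consistent
    return(rep(min(max(mean, lower), upper), n))
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}
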
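# Internal error helpers: validation errors carry a dedicated condition class so
# the CLI can map them to exit status 2, while anything else is "internal" (1).

qeps_validation_error <- function(msg, call. = FALSE) {
  stop(errorCondition(msg, class = c("qeps_validation_error", "qeps_error")))
}

qeps_domain_error <- function(msg) {
  stop(errorCondition(msg, class = c("qeps_domain_error", "qeps_error")))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    qeps_validation_error(sprintf("non-finite value in %s", what))
  }
  invisible(x)
}

# Central-difference Jacobian of a vector-valued function, used for the
# asymptotic covariance of the penalized fit. Step scaled per coordinate.
num_jacobian <- function(fn, x, h = 1e-6) {
  f0 <- fn(x)
  J <- matrix(NA_real_, nrow = length(f0), ncol = length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (fn(xp) - fn(xm)) / (2 * hj)
  }
  J
}

# Deterministic sub-seed derivation: keeps every derived seed a valid 32-bit
# integer whatever small integer the caller supplies.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
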
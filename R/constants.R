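#' Sex-specific QEPS shape constants
#'
#' The QEPS model is shape invariant: the four basis functions have fixed
#' shapes shared by a whole cohort, and individuals differ only through the
#' six modifying parameters of [qeps_params()]. The shape constants pin down
#' those shared shapes:
#'
#' * `t0` — origin of growth in years relative to birth (negative; roughly
#'   six weeks after conception for a term birth),
#' * `U` — horizon of the quadratic basis in years (the Q velocity declines
#'   linearly to zero at age `t0 + U`),
#' * `sP` — dimensionless width of the pubertal basis on the scaled-age axis
#'   (sex specific; controls spurt duration relative to its timing),
#' * `xS` — scaled age at which the stop basis switches on,
#' * `wS` — dimensionless width of the stop basis,
#' * `adult_eval_age` — age in years at which component maxima are read off.
#'
#' Defaults are calibrated so that, at the cohort-mean time-scale parameter,
#' the model reproduces the reference cohort's mean pubertal duration
#' (AgeP5 to AgeP95 of 4.80 y for girls, 4.32 y for boys) and the observed
#' fraction of pubertal growth completed when the stop function starts
#' (about 74% for girls, 89% for boys).
#'
#' @param sex `"F"` or `"M"`.
#' @param ... named overrides for any constant.
#' @return An object of class `qeps_constants` (a named list).
#' @examples
#' qeps_constants("F")
#' qeps_constants("M", adult_eval_age = 22)
#' @export
qeps_constants <- function(sex = c("F", "M"), ...) {
  sex <- match.arg(sex)
  base <- list(
    t0 = -0.65,
    U = 20.65,
    sP = if (sex == "F") 0.0770 else 0.0611,
    xS = if (sex == "F") 1.072 else 1.118,
    wS = 0.15,
    adult_eval_age = 20
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown)) {
    qeps_validation_error(paste("unknown shape constant(s):",
                                paste(unknown, collapse = ", ")))
  }
  base[names(dots)] <- dots
  base$sex <- sex
  validate_constants(structure(base, class = "qeps_constants"))
}

validate_constants <- function(const) {
  if (!(const$t0 < 0)) qeps_validation_error("t0 must be negative (prenatal origin)")
  if (!(const$adult_eval_age > 0)) qeps_validation_error("adult_eval_age must be positive")
  if (!(const$U > 0)) qeps_validation_error("U must be positive")
  if (!(const$sP > 0)) qeps_validation_error("sP must be positive")
  if (!(const$wS > 0)) qeps_validation_error("wS must be positive")
  if (!(const$xS > 0)) qeps_validation_error("xS must be positive")
  stopifnot_finite(unlist(const[CONSTANT_KEYS]), "shape constants")
  const
}

CONSTANT_KEYS <- c("t0", "U", "sP", "xS", "wS", "adult_eval_age")

#' @export
print.qeps_constants <- function(x, ...) {
  cat(sprintf("QEPS shape constants (sex %s):\n", x$sex))
  for (k in CONSTANT_KEYS) cat(sprintf("  %-15s %g\n", k, x[[k]]))
  invisible(x)
}
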
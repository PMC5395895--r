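#' The six individual QEPS modifying parameters
#'
#' Each individual's growth curve is obtained from the shared basis shapes by
#' four height-scale parameters and two time-scale parameters — six free
#' parameters in total:
#'
#' * `hQ` (cm) — height scale of the quadratic basis (adult Q contribution),
#' * `hE` (cm) — height scale of the exponential infancy basis,
#' * `thetaE` (years) — time scale of the exponential basis,
#' * `hP` (cm) — height scale of the pubertal basis; its asymptote, so the
#'   specific pubertal gain Pmax. `hP = 0` encodes an absent spurt,
#' * `thetaP` (years) — time scale of the pubertal (and stop) basis; the
#'   mid-spurt age is `t0 + thetaP`,
#' * `hS` (cm) — height scale of the stop basis.
#'
#' @param hQ,hE,thetaE,hP,thetaP,hS numeric scalars, see above.
#' @return An object of class `qeps_params` (a named numeric vector).
#' @examples
#' # cohort-mean girl
#' qeps_params(hQ = 97.61, hE = 62.86, thetaE = 0.54,
#'             hP = 12.78, thetaP = 12.74, hS = 5.99)
#' @export
qeps_params <- function(hQ, hE, thetaE, hP, thetaP, hS) {
  p <- c(hQ = hQ, hE = hE, thetaE = thetaE, hP = hP, thetaP = thetaP, hS = hS)
  validate_params(structure(p, class = "qeps_params"))
}

PARAM_KEYS <- c("hQ", "hE", "thetaE", "hP", "thetaP", "hS")

validate_params <- function(p) {
  stopifnot_finite(unclass(p), "QEPS parameters")
  if (p[["hQ"]] <= 0) qeps_validation_error("hQ must be positive")
  if (p[["hE"]] <= 0) qeps_validation_error("hE must be positive")
  if (p[["thetaE"]] <= 0) qeps_validation_error("thetaE must be positive")
  if (p[["hP"]] < 0) qeps_validation_error("hP must be nonnegative")
  if (p[["thetaP"]] <= 0) qeps_validation_error("thetaP must be positive")
  if (p[["hS"]] < 0) qeps_validation_error("hS must be nonnegative")
  p
}

as_qeps_params <- function(x) {
  if (inherits(x, "qeps_params")) return(x)
  x <- unlist(x)
  if (!all(PARAM_KEYS %in% names(x))) {
    qeps_validation_error(paste("parameter vector must name:",
                                paste(PARAM_KEYS, collapse = ", ")))
  }
  validate_params(structure(x[PARAM_KEYS], class = "qeps_params"))
}

#' Default cohort-mean parameters per sex
#'
#' Convenience constructor returning the population-mean parameter set used
#' throughout the documentation and as fitting prior location; values come
#' from [default_population_model()].
#'
#' @param sex `"F"` or `"M"`.
#' @return A `qeps_params` object.
#' @export
qeps_default_params <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  pm <- default_population_model(sex)
  do.call(qeps_params, as.list(setNames(pm$moments$mean, pm$moments$param)))
}

#' @export
print.qeps_params <- function(x, ...) {
  cat("QEPS individual parameters:\n")
  print(round(unclass(x), 4))
  invisible(x)
}
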
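# Canonical QEPS basis shapes. With u = age - t0 and scaled age x = u/thetaP:
#   E(u) = hE * (1 - exp(-u/thetaE))                       (infancy, saturating)
#   Q(u) = hQ * (2v - v^2), v = min(u/U, 1)                (childhood, linear HV decline)
#   P(x) = hP * logistic(z)^2, z = (x-1)/sP + z50          (pubertal spurt)
#   S(x) = hS * y^2/(1+y^2), y = (x-xS)/wS for x > xS      (stop; 0 before xS)
# z50 = ln(1+sqrt(2)) makes P(x = 1) = hP/2 exactly, so AgeP50 = t0 + thetaP.
# All bases vanish at u = 0; T = Q + E + P - S.

Z50 <- log(1 + sqrt(2))

#' Evaluate the QEPS components
#'
#' Evaluates the six component series Q, E, P, S, QES = Q + E - S and
#' T = Q + E + P - S at the requested derivative order on a vector of ages:
#' order 0 gives heights in cm, order 1 height velocities in cm/year, order 2
#' height accelerations in cm/year^2. All derivatives are closed-form.
#'
#' @param params a [qeps_params()] object (or coercible named vector).
#' @param constants a [qeps_constants()] object.
#' @param ages numeric vector of decimal ages in years since birth; every age
#'   must be at or after the growth origin `constants$t0`.
#' @param order derivative order, 0, 1 or 2.
#' @return A data frame with columns `age`, `Q`, `E`, `P`, `S`, `QES`, `T`.
#' @examples
#' girl <- qeps_default_params("F")
#' qeps_evaluate(girl, qeps_constants("F"), ages = c(0, 1, 10, 12, 18))
#' @export
qeps_evaluate <- function(params, constants, ages, order = 0) {
  params <- as_qeps_params(params)
  if (!order %in% 0:2) qeps_validation_error("order must be 0, 1 or 2")
  if (!is.numeric(ages) || !all(is.finite(ages))) {
    qeps_validation_error("ages must be finite numeric")
  }
  if (any(ages < constants$t0)) {
    qeps_domain_error(sprintf("age before growth origin t0 = %g", constants$t0))
  }
  comp <- eval_components(params, constants, ages, order)
  data.frame(age = ages, Q = comp$Q, E = comp$E, P = comp$P, S = comp$S,
             QES = comp$Q + comp$E - comp$S,
             T = comp$Q + comp$E + comp$P - comp$S)
}

# Unchecked fast path shared by the public evaluator, the fitting residual
# function and the landmark root finders.
eval_components <- function(params, constants, ages, order = 0) {
  u <- ages - constants$t0
  hQ <- params[["hQ"]]; hE <- params[["hE"]]; thetaE <- params[["thetaE"]]
  hP <- params[["hP"]]; thetaP <- params[["thetaP"]]; hS <- params[["hS"]]
  U <- constants$U; sP <- constants$sP; xS <- constants$xS; wS <- constants$wS

  # E basis
  eu <- exp(-u / thetaE)
  E <- switch(as.character(order),
    "0" = hE * (1 - eu),
    "1" = hE / thetaE * eu,
    "2" = -hE / thetaE^2 * eu)

  # Q basis, velocity capped to zero past u = U
  v <- pmin(u / U, 1)
  inside <- u < U
  Q <- switch(as.character(order),
    "0" = hQ * (2 * v - v^2),
    "1" = ifelse(inside, hQ * 2 / U * (1 - v), 0),
    "2" = ifelse(inside, rep(-2 * hQ / U^2, length(u)), 0))

  # P basis (squared logistic on scaled age)
  x <- u / thetaP
  z <- (x - 1) / sP + Z50
  L <- plogis(z)
  kP <- 1 / (sP * thetaP)
  P <- switch(as.character(order),
    "0" = hP * L^2,
    "1" = 2 * hP * kP * L^2 * (1 - L),
    "2" = 2 * hP * kP^2 * L^2 * (1 - L) * (2 - 3 * L))

  # S basis (C1 at xS; curvature jump there is the HA break)
  y <- pmax(x - xS, 0) / wS
  kS <- 1 / (wS * thetaP)
  S <- switch(as.character(order),
    "0" = hS * y^2 / (1 + y^2),
    "1" = hS * kS * 2 * y / (1 + y^2)^2,
    "2" = hS * kS^2 * ifelse(x > xS, (2 - 6 * y^2) / (1 + y^2)^3, 0))

  list(Q = Q, E = E, P = P, S = S)
}

#' Component maxima at the adult evaluation age
#'
#' Reads off each component's contribution to adult height at
#' `constants$adult_eval_age` (default 20 years). The additive identity
#' `Tmax = Emax + Qmax + Pmax - Smax` holds exactly by construction.
#'
#' @inheritParams qeps_evaluate
#' @return A named list with `Emax`, `Qmax`, `Pmax`, `Smax`, `Tmax` in cm.
#' @examples
#' component_maxima(qeps_default_params("M"), qeps_constants("M"))
#' @export
component_maxima <- function(params, constants) {
  cv <- qeps_evaluate(params, constants, constants$adult_eval_age, order = 0)
  list(Emax = cv$E, Qmax = cv$Q, Pmax = cv$P, Smax = cv$S, Tmax = cv$T)
}

# Scalar total-curve height / velocity / acceleration helpers used by the
# fitting residual function and the landmark root finders.
qeps_total <- function(params, constants, ages, order = 0) {
  comp <- eval_components(params, constants, ages, order)
  comp$Q + comp$E + comp$P - comp$S
}

qeps_velocity <- function(params, constants, ages) {
  qeps_total(params, constants, ages, order = 1)
}

qeps_acceleration <- function(params, constants, ages) {
  qeps_total(params, constants, ages, order = 2)
}
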
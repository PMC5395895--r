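#' Age at which the pubertal component reaches a given fraction of its gain
#'
#' Closed-form inversion of the squared-logistic pubertal basis: the age `a`
#' with `P(a) = q * hP` is `t0 + thetaP * (1 + sP * (logit(sqrt(q)) - z50))`
#' with `z50 = ln(1 + sqrt(2))`. No grid search is involved.
#'
#' @inheritParams qeps_evaluate
#' @param q fraction of the total pubertal gain, strictly between 0 and 1.
#' @return Age in years.
#' @examples
#' girl <- qeps_default_params("F")
#' age_at_p_fraction(girl, qeps_constants("F"), 0.5)   # AgeP50 = t0 + thetaP
#' @export
age_at_p_fraction <- function(params, constants, q) {
  params <- as_qeps_params(params)
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1)) {
    qeps_validation_error("q must lie strictly in (0, 1)")
  }
  if (params[["hP"]] <= 0) {
    qeps_validation_error("no pubertal spurt (hP = 0): percentile ages undefined")
  }
  zq <- qlogis(sqrt(q))
  constants$t0 + params[["thetaP"]] * (1 + constants$sP * (zq - Z50))
}

#' Landmarks of the pubertal component
#'
#' Computes the percentile ages AgeP1/5/50/95/99, the age at peak velocity of
#' the P component (where the logistic value is 2/3, so P is at 4/9 of its
#' gain), and the stop-onset age `AgeS0 = t0 + thetaP * xS`. When `hP = 0`
#' the spurt is absent: all ages are `NA` and the `no_spurt` flag is set.
#'
#' @inheritParams qeps_evaluate
#' @return A named list of ages plus a character vector `flags`.
#' @export
p_landmarks <- function(params, constants) {
  params <- as_qeps_params(params)
  thetaP <- params[["thetaP"]]
  if (params[["hP"]] <= 0) {
    out <- as.list(rep(NA_real_, 7))
    names(out) <- c("AgeP1", "AgeP5", "AgeP50", "AgeP95", "AgeP99",
                    "AgeP_phv", "AgeS0")
    out$AgeS0 <- constants$t0 + thetaP * constants$xS
    out$flags <- "no_spurt"
    return(out)
  }
  qs <- c(AgeP1 = 0.01, AgeP5 = 0.05, AgeP50 = 0.50,
          AgeP95 = 0.95, AgeP99 = 0.99)
  ages <- vapply(qs, function(q) age_at_p_fraction(params, constants, q),
                 numeric(1))
  # P'(age) is maximal where d/dz [L^2 (1-L)] = 0 => L = 2/3 => z = ln 2
  age_phv <- constants$t0 +
    thetaP * (1 + constants$sP * (log(2) - Z50))
  c(as.list(ages),
    list(AgeP_phv = age_phv,
         AgeS0 = constants$t0 + thetaP * constants$xS,
         flags = character(0)))
}

#' Landmarks of the total growth curve
#'
#' Onset of puberty is the interior minimum of total height velocity before
#' the spurt, mid-puberty the peak height velocity (both roots of the
#' acceleration), and end of puberty the age past PHV at which velocity has
#' fallen to 1 cm/year. Candidates are bracketed on a 0.01-year grid and
#' refined with a bracketing root finder. When the velocity has no interior
#' minimum in the window (tiny or absent spurt), onset and PHV are flagged
#' undetectable rather than forced.
#'
#' @inheritParams qeps_evaluate
#' @param window numeric length-2 search window in years (default `c(3, 25)`,
#'   excluding the infancy velocity spike).
#' @return A named list `AgeT_onset`, `AgeT_phv`, `AgeT_end` plus `flags`.
#' @export
t_landmarks <- function(params, constants, window = c(3, 25)) {
  params <- as_qeps_params(params)
  if (length(window) != 2 || window[1] >= window[2]) {
    qeps_validation_error("window must be an increasing age interval")
  }
  grid <- seq(window[1], window[2], by = 0.01)
  hv <- qeps_velocity(params, constants, grid)
  acc <- function(a) qeps_acceleration(params, constants, a)
  vel <- function(a) qeps_velocity(params, constants, a)

  flags <- character(0)
  onset <- phv <- NA_real_

  # Interior local extrema of the velocity. The childhood velocity decline
  # can exceed PHV, so the global argmax is not the spurt peak: PHV is the
  # largest interior local maximum whose velocity still exceeds the
  # 1 cm/year end-of-puberty threshold (a "peak" below that is the stop
  # function's tail, not a growth spurt), and onset is the deepest local
  # minimum preceding it.
  d <- diff(hv)
  i_mins <- which(d[-length(d)] < 0 & d[-1] > 0) + 1L
  i_maxs <- which(d[-length(d)] > 0 & d[-1] < 0) + 1L
  # A genuine spurt has its onset minimum while growth is still ongoing
  # (velocity above the 1 cm/yr end threshold) and its peak above that
  # threshold too; the stop function's velocity tail fails both.
  i_mins <- i_mins[hv[i_mins] > 1]
  i_maxs <- i_maxs[hv[i_maxs] > 1]
  i_phv <- NA_integer_
  if (length(i_mins) && length(i_maxs)) {
    cands <- i_maxs[vapply(i_maxs, function(i) any(i_mins < i), logical(1))]
    if (length(cands)) {
      i_phv <- cands[which.max(hv[cands])]
      pre <- i_mins[i_mins < i_phv]
      i_on <- pre[which.min(hv[pre])]
      onset <- uniroot(acc, lower = grid[i_on - 1L], upper = grid[i_on + 1L],
                       tol = 1e-10)$root
      phv <- uniroot(acc, lower = grid[i_phv - 1L], upper = grid[i_phv + 1L],
                     tol = 1e-10)$root
    }
  }
  if (is.na(phv)) flags <- c(flags, "onset_undetectable", "phv_undetectable")

  # First downcrossing of HV = 1 cm/yr after PHV (from the window start
  # when no PHV is detectable, the velocity then declining through 1).
  j0 <- if (is.na(phv)) 2L else i_phv
  below <- which(hv < 1 & seq_along(hv) >= j0 & c(Inf, hv[-length(hv)]) >= 1)
  if (!length(below)) {
    qeps_domain_error("height velocity never decreases to 1 cm/year in window: non-plateauing parameters")
  }
  j <- below[1]
  aend <- uniroot(function(a) vel(a) - 1, lower = grid[j - 1L], upper = grid[j],
                  tol = 1e-10)$root

  list(AgeT_onset = onset, AgeT_phv = phv, AgeT_end = aend, flags = flags)
}

#' Height gains over an age interval, decomposed into P and QES parts
#'
#' Additivity of the model gives `Tgain = Pgain + QESgain` exactly for any
#' interval.
#'
#' @inheritParams qeps_evaluate
#' @param a0,a1 interval endpoints in years, `a0 <= a1`.
#' @return Named list `Tgain`, `Pgain`, `QESgain` in cm.
#' @export
interval_gains <- function(params, constants, a0, a1) {
  if (!is.finite(a0) || !is.finite(a1) || a1 < a0) {
    qeps_validation_error("need finite interval endpoints with a1 >= a0")
  }
  cv <- qeps_evaluate(params, constants, c(a0, a1), order = 0)
  pg <- cv$P[2] - cv$P[1]
  qg <- cv$QES[2] - cv$QES[1]
  list(Tgain = pg + qg, Pgain = pg, QESgain = qg)
}

# Names of the numeric variables a pubertal summary carries, in output order.
SUMMARY_VARS <- c("AgeT_onset", "AgeT_phv", "AgeT_end",
                  "AgeP1", "AgeP5", "AgeP50", "AgeP95", "AgeP99",
                  "AgeP_phv", "AgeS0",
                  "Pmax", "Emax", "Qmax", "Smax", "Tmax",
                  "Tpubgain", "Ppubgain", "QESpubgain",
                  "dP5_95", "dP1_99", "dTonset_end")

#' Full pubertal summary for one parameter set
#'
#' Assembles every landmark age, component maximum, pubertal duration and
#' gain variable. The pubertal gain `Ppubgain` is 95% of the asymptotic
#' pubertal gain `hP`; `Tpubgain` and `QESpubgain` are taken over the
#' interval from AgeP5 to the age where P reaches 99.9% of its gain (a
#' bounded stand-in for "100% of the pubertal function", accurate to under
#' 0.1% of `hP`). Degenerate inputs set flags; the function never aborts,
#' so cohort runs can proceed.
#'
#' @inheritParams t_landmarks
#' @return An object of class `qeps_summary`: a named list of the variables
#'   in `SUMMARY_VARS` plus a character vector `flags` (possible tokens:
#'   `no_spurt`, `onset_undetectable`, `phv_undetectable`).
#' @examples
#' pubertal_summary(qeps_default_params("F"), qeps_constants("F"))
#' @export
pubertal_summary <- function(params, constants, window = c(3, 25)) {
  params <- as_qeps_params(params)
  pl <- p_landmarks(params, constants)
  tl <- tryCatch(t_landmarks(params, constants, window),
                 qeps_domain_error = function(e) {
                   list(AgeT_onset = NA_real_, AgeT_phv = NA_real_,
                        AgeT_end = NA_real_, flags = "end_undetectable")
                 })
  cm <- component_maxima(params, constants)
  flags <- unique(c(pl$flags, tl$flags))
  hP <- params[["hP"]]

  if (hP > 0) {
    a100 <- age_at_p_fraction(params, constants, 0.999)
    g <- interval_gains(params, constants, pl$AgeP5, a100)
    tpub <- g$Tgain; qespub <- g$QESgain
    dP5_95 <- pl$AgeP95 - pl$AgeP5
    dP1_99 <- pl$AgeP99 - pl$AgeP1
  } else {
    tpub <- qespub <- NA_real_
    dP5_95 <- dP1_99 <- NA_real_
  }

  out <- list(
    AgeT_onset = tl$AgeT_onset, AgeT_phv = tl$AgeT_phv, AgeT_end = tl$AgeT_end,
    AgeP1 = pl$AgeP1, AgeP5 = pl$AgeP5, AgeP50 = pl$AgeP50,
    AgeP95 = pl$AgeP95, AgeP99 = pl$AgeP99,
    AgeP_phv = pl$AgeP_phv, AgeS0 = pl$AgeS0,
    Pmax = cm$Pmax, Emax = cm$Emax, Qmax = cm$Qmax, Smax = cm$Smax,
    Tmax = cm$Tmax,
    Tpubgain = tpub, Ppubgain = if (hP > 0) 0.95 * hP else 0,
    QESpubgain = qespub,
    dP5_95 = dP5_95, dP1_99 = dP1_99,
    dTonset_end = tl$AgeT_end - tl$AgeT_onset,
    flags = flags
  )
  structure(out, class = "qeps_summary")
}

#' @export
print.qeps_summary <- function(x, ...) {
  cat("QEPS pubertal summary:\n")
  v <- unlist(x[SUMMARY_VARS])
  print(round(v, 3))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# Numeric vector view of a summary (used by bootstrap and cohort tables).
summary_to_vector <- function(s) {
  vapply(SUMMARY_VARS, function(v) {
    val <- s[[v]]
    if (is.null(val) || length(val) != 1L) NA_real_ else as.numeric(val)
  }, numeric(1))
}

#' Cohort landmark table
#'
#' Applies [pubertal_summary()] over a list of fitted individuals (or raw
#' parameter sets) and returns one row per subject with the summary columns
#' and a semicolon-separated `flags` column.
#'
#' @param fits list of `qeps_fit` objects, or list of `qeps_params`.
#' @param constants used only when `fits` are raw parameter sets.
#' @param ids optional subject ids (taken from fits when present).
#' @return A data frame.
#' @export
cohort_landmarks <- function(fits, constants = NULL, ids = NULL) {
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (inherits(f, "qeps_fit")) {
      s <- pubertal_summary(f$params, f$constants)
      id <- f$subject_id
    } else {
      s <- pubertal_summary(f, constants)
      id <- if (is.null(ids)) sprintf("subject_%d", i) else ids[i]
    }
    cbind(data.frame(subject_id = id, stringsAsFactors = FALSE),
          as.data.frame(as.list(summary_to_vector(s))),
          data.frame(flags = paste(s$flags, collapse = ";"),
                     stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
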
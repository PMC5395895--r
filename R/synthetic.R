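# Synthetic cohorts emulating a 1970s Gothenburg-style school-health study:
# per-subject true QEPS parameters drawn from sex-specific population models
# calibrated to published cohort moments, a visit schedule covering the eight
# selection epochs (birth; >= 2 infancy visits; one or more visits per later
# epoch), and Gaussian measurement noise (larger for supine infant length).

#' Default per-sex population model for the generator
#'
#' Marginal moments are calibrated to published cohort tables: natural-scale
#' mean/SD of `hQ` (97.61/7.57 girls, 104.05/8.02 boys), `hE` (62.86/2.87,
#' 65.08/2.88) and `hP` (12.78/3.65, 17.34/3.63); `thetaP` is centred so the
#' mid-spurt age t0 + thetaP matches the mean AgeP50 (12.74/0.95 girls,
#' 14.45/0.96 boys); mean `hS` follows from the adult-height identity
#' Tmax = Emax + Qmax + Pmax - Smax (5.99 girls, 6.04 boys; SD 0.60 chosen);
#' `thetaE` (0.54/0.05 y girls, 0.58/0.05 y boys) is calibrated so the
#' simulated birth length matches the cohort's printed mean (49.9 / 50.5 cm)
#' without inflating its SD, which also makes infancy growth ~95% complete
#' by about 1 year of age.
#' Height scales and `thetaE` are log-normal; `thetaP` is normal on the
#' natural scale truncated at 3 SD. Dependence is a Gaussian copula whose only
#' nonzero off-diagonal is cor(hP, hQ) = -0.60 (girls) / -0.53 (boys),
#' reflecting the published negative regression of pubertal gain on Qmax;
#' hP and thetaP are uncorrelated (pubertal gain independent of timing).
#'
#' @param sex `"F"` or `"M"`.
#' @return An object of class `qeps_popmodel` with elements `sex`,
#'   `moments` (data frame: param, mean, sd, dist), `corr` (6x6 matrix).
#' @export
default_population_model <- function(sex = c("F", "M")) {
  sex <- match.arg(sex)
  if (sex == "F") {
    moments <- data.frame(
      param = PARAM_KEYS,
      mean = c(97.61, 62.86, 0.54, 12.78, 12.74, 5.99),
      sd   = c(7.57,  2.87, 0.05,  3.65,  0.95, 0.60),
      dist = c("lognormal", "lognormal", "lognormal", "lognormal",
               "normal_trunc3", "lognormal"),
      stringsAsFactors = FALSE)
    r_hp_hq <- -0.60
  } else {
    moments <- data.frame(
      param = PARAM_KEYS,
      mean = c(104.05, 65.08, 0.58, 17.34, 14.45, 6.04),
      sd   = c(8.02,   2.88, 0.05,  3.63,  0.96, 0.60),
      dist = c("lognormal", "lognormal", "lognormal", "lognormal",
               "normal_trunc3", "lognormal"),
      stringsAsFactors = FALSE)
    r_hp_hq <- -0.53
  }
  corr <- diag(6)
  dimnames(corr) <- list(PARAM_KEYS, PARAM_KEYS)
  corr["hP", "hQ"] <- corr["hQ", "hP"] <- r_hp_hq
  validate_popmodel(structure(list(sex = sex, moments = moments, corr = corr),
                              class = "qeps_popmodel"))
}

validate_popmodel <- function(pm) {
  if (any(pm$moments$sd <= 0)) qeps_validation_error("population SDs must be positive")
  corr <- pm$corr
  if (!isTRUE(all.equal(corr, t(corr))) || any(abs(diag(corr) - 1) > 1e-12)) {
    qeps_validation_error("correlation matrix must be symmetric with unit diagonal")
  }
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) qeps_validation_error("correlation matrix must be positive definite")
  pm
}

# Draw n parameter vectors from a population model (uses the current RNG
# stream). thetaP draws outside +/- 3 SD are rejected and redrawn jointly.
draw_parameters <- function(pm, n) {
  Lc <- chol(pm$corr)
  m <- pm$moments
  draw_z <- function(k) matrix(rnorm(k * 6), k, 6) %*% Lc
  z <- draw_z(n)
  i_thetaP <- match("thetaP", m$param)
  repeat {
    bad <- which(abs(z[, i_thetaP]) > 3)
    if (!length(bad)) break
    z[bad, ] <- draw_z(length(bad))
  }
  out <- matrix(NA_real_, n, 6, dimnames = list(NULL, m$param))
  for (j in seq_len(6)) {
    mu <- m$mean[j]; s <- m$sd[j]
    if (m$dist[j] == "lognormal") {
      sdlog <- sqrt(log(1 + (s / mu)^2))
      mulog <- log(mu) - sdlog^2 / 2
      out[, j] <- exp(mulog + sdlog * z[, j])
    } else {
      out[, j] <- mu + s * z[, j]
    }
  }
  out
}

#' Measurement schedule for one synthetic subject
#'
#' Returns a sorted vector of visit ages covering the eight study epochs
#' (birth; two infancy visits before 9 months; then toddler 0.75-3.5 y,
#' child 3.5-6 y, school 6-9 y, juvenile 9-12 y, adolescent 12-16 y,
#' adult >= 16 y), roughly annual from toddlerhood as in school-health
#' records, with uniform +/- 0.1-year jitter on every visit except birth.
#' `"dense"` adds quarterly visits between 9 and 16 years; `"sparse"`
#' drops all visits of one randomly chosen epoch among toddler, child,
#' school, juvenile and adolescent.
#'
#' @param seed optional integer; when `NULL` the current RNG stream is used.
#' @param density `"sparse"`, `"standard"` or `"dense"`.
#' @return Numeric vector of ages in years.
#' @export
measurement_schedule <- function(seed = NULL, density = c("standard", "sparse", "dense")) {
  density <- match.arg(density)
  if (!is.null(seed)) set.seed(seed)
  base <- list(
    birth      = 0,
    infant     = c(0.25, 0.5),
    toddler    = c(1.0, 1.8, 3.0),
    child      = c(4.0, 5.0),
    school     = c(6.5, 7.5, 8.5),
    juvenile   = c(9.5, 10.5, 11.5),
    adolescent = c(12.5, 13.25, 14.0, 15.0),
    adult      = c(16.5, 17.5, 19.0)
  )
  if (density == "sparse") {
    droppable <- c("toddler", "child", "school", "juvenile", "adolescent")
    base[[sample(droppable, 1)]] <- NULL
  }
  ages <- unlist(base, use.names = FALSE)
  jitter <- runif(length(ages), -0.1, 0.1)
  jitter[ages == 0] <- 0
  ages <- ages + jitter
  if (density == "dense") ages <- c(ages, seq(9, 16, by = 0.25))
  sort(ages)
}

#' Add measurement noise to exact model heights
#'
#' Independent Gaussian noise with SD `sd_infant` (default 0.45 cm, supine
#' length) below `infant_age` years and `sd_child` (default 0.27 cm,
#' standing height) at or above it.
#'
#' @param true_heights,ages equal-length numeric vectors.
#' @param seed optional integer; `NULL` uses the current RNG stream.
#' @param sd_infant,sd_child,infant_age noise model constants.
#' @return Numeric vector of noisy heights in cm.
#' @export
add_noise <- function(true_heights, ages, seed = NULL,
                      sd_infant = 0.45, sd_child = 0.27, infant_age = 2) {
  if (length(true_heights) != length(ages)) {
    qeps_validation_error("true_heights and ages must have equal length")
  }
  if (!is.null(seed)) set.seed(seed)
  sds <- ifelse(ages < infant_age, sd_infant, sd_child)
  true_heights + rnorm(length(ages), 0, sds)
}

#' Simulate a synthetic cohort with stored truth
#'
#' Draws per-subject true parameters from the per-sex population models,
#' builds a measurement schedule and noisy heights for each subject, and
#' stores the true parameters and true pubertal summary alongside the
#' measurement record. Fully reproducible from `seed`.
#'
#' @param n number of subjects (>= 1).
#' @param sex_ratio fraction of girls (default 0.5; girl count is
#'   `round(n * sex_ratio)`).
#' @param popmodel_F,popmodel_M population models per sex.
#' @param seed integer seed (required).
#' @param density measurement schedule density, see [measurement_schedule()].
#' @param sd_infant,sd_child measurement noise SDs in cm.
#' @param compute_truth_summary if `TRUE` (default) each subject carries its
#'   true [pubertal_summary()]; disable to speed up large draws when only
#'   parameters are needed.
#' @return An object of class `qeps_cohort`: a list of subjects, each a list
#'   with `record` (a `qeps_record`), `true_params`, `true_summary`.
#' @examples
#' coh <- sample_cohort(3, seed = 1)
#' coh[[1]]$record
#' @export
sample_cohort <- function(n, sex_ratio = 0.5,
                          popmodel_F = default_population_model("F"),
                          popmodel_M = default_population_model("M"),
                          seed, density = "standard",
                          sd_infant = 0.45, sd_child = 0.27,
                          compute_truth_summary = TRUE) {
  if (missing(seed)) qeps_validation_error("seed is required for reproducibility")
  if (!is.numeric(n) || n < 1) qeps_validation_error("n must be >= 1")
  n <- as.integer(n)
  validate_popmodel(popmodel_F); validate_popmodel(popmodel_M)
  set.seed(seed)

  n_f <- round(n * sex_ratio)
  sexes <- c(rep("F", n_f), rep("M", n - n_f))
  pars_f <- if (n_f > 0) draw_parameters(popmodel_F, n_f)
  pars_m <- if (n - n_f > 0) draw_parameters(popmodel_M, n - n_f)
  pars <- rbind(pars_f, pars_m)

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- sexes[i]
    const <- qeps_constants(sex)
    p <- as_qeps_params(pars[i, ])
    ages <- measurement_schedule(seed = NULL, density = density)
    truth <- qeps_evaluate(p, const, ages, order = 0)$T
    heights <- add_noise(truth, ages, seed = NULL,
                         sd_infant = sd_infant, sd_child = sd_child)
    record <- growth_record(sprintf("S%04d", i), sex,
                            age_years = ages, height_cm = heights)
    subjects[[i]] <- list(
      record = record,
      true_params = p,
      true_summary = if (compute_truth_summary) pubertal_summary(p, const) else NULL
    )
  }
  structure(subjects, class = "qeps_cohort",
            seed = seed, density = density, sex_ratio = sex_ratio)
}

#' @export
print.qeps_cohort <- function(x, ...) {
  cat(sprintf("Synthetic QEPS cohort: %d subjects (%d girls), density '%s', seed %s\n",
              length(x), sum(vapply(x, function(s) s$record$sex == "F", logical(1))),
              attr(x, "density"), attr(x, "seed")))
  invisible(x)
}

#' True-parameter and true-landmark table of a synthetic cohort
#'
#' @param cohort a `qeps_cohort`.
#' @return Data frame with one row per subject: id, sex, the six true
#'   parameters, and the true landmark variables when stored.
#' @export
cohort_truth <- function(cohort) {
  rows <- lapply(cohort, function(s) {
    base <- data.frame(subject_id = s$record$subject_id, sex = s$record$sex,
                       stringsAsFactors = FALSE)
    pars <- as.data.frame(as.list(unclass(s$true_params)))
    if (!is.null(s$true_summary)) {
      sv <- as.data.frame(as.list(summary_to_vector(s$true_summary)))
      names(sv) <- paste0("true_", names(sv))
      cbind(base, pars, sv)
    } else cbind(base, pars)
  })
  do.call(rbind, rows)
}
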
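#' Per-sex log-scale priors for penalized fitting
#'
#' Location/scale of each parameter on the log scale, derived by moment
#' matching from the same published cohort moments that calibrate
#' [default_population_model()]. Used as ridge-penalty centres and as
#' multi-start locations.
#'
#' @param sex `"F"` or `"M"`.
#' @return Data frame with columns `param`, `mu_log`, `sigma_log`.
#' @export
qeps_priors <- function(sex = c("F", "M")) {
  pm <- default_population_model(match.arg(sex))
  m <- pm$moments
  sdlog <- sqrt(log(1 + (m$sd / m$mean)^2))
  data.frame(param = m$param,
             mu_log = log(m$mean) - sdlog^2 / 2,
             sigma_log = sdlog,
             stringsAsFactors = FALSE)
}

# Default measurement weights: supine-length measurements (age < 2 y) carry
# the larger error SD of the noise model, so they get the corresponding
# inverse-variance relative weight; weights are relative to the standing-
# height error scale, making residual_sd comparable to sd_child.
default_fit_weights <- function(ages, sd_infant = 0.45, sd_child = 0.27,
                                infant_age = 2) {
  ifelse(ages < infant_age, (sd_child / sd_infant)^2, 1)
}

#' Fit the QEPS curve to one subject
#'
#' Penalized nonlinear least squares on the six parameters in log space:
#' minimizes `sum_i w_i (h_i - T(a_i))^2 +
#' lambda * sum_j ((log b_j - mu_j) / sigma_j)^2` by Levenberg-Marquardt
#' (three deterministic starts: the prior mean and the prior mean shifted by
#' +/- 0.5 prior SD on `thetaP`; best objective kept). The log
#' parameterization enforces positivity without constraints; the ridge
#' penalty (default `lambda = 0.01 * n_points`) stabilizes weakly identified
#' parameters on sparse records and vanishes asymptotically. The parameter
#' covariance is the asymptotic covariance from the Jacobian of the
#' penalized residual vector at the optimum.
#'
#' @param record a [growth_record()] with at least 6 measurements.
#' @param constants shape constants; default those for the record's sex.
#' @param priors per-sex prior table as from [qeps_priors()].
#' @param penalty_weight ridge weight `lambda`; `NULL` or `NA` gives
#'   `0.01 * n_points`.
#' @param weights per-measurement weights; `NULL` gives the error-model
#'   default (infant measurements downweighted by the known variance ratio);
#'   pass `rep(1, n)` for uniform weights.
#' @param seed integer; kept in the fit for reproducibility metadata (the
#'   optimizer itself is deterministic).
#' @return An object of class `qeps_fit`: `params`, `constants`, `logpar`,
#'   `cov` (6x6, log scale), `residual_sd` (cm), `n_points`, `converged`,
#'   `penalty_used`, `residuals`, `weights`, `subject_id`, `sex`, `record`.
#' @export
fit_individual <- function(record, constants = NULL, priors = NULL,
                           penalty_weight = NULL, weights = NULL, seed = 1L) {
  if (!inherits(record, "qeps_record")) {
    qeps_validation_error("record must be a qeps_record")
  }
  m <- record$measurements
  n <- nrow(m)
  if (n < 6) {
    qeps_validation_error(sprintf(
      "subject %s: %d measurements; at least 6 are required to fit 6 parameters",
      record$subject_id, n))
  }
  constants <- constants %||% qeps_constants(record$sex)
  priors <- priors %||% qeps_priors(record$sex)
  lambda <- penalty_weight
  if (is.null(lambda) || is.na(lambda)) lambda <- 0.01 * n
  w <- weights %||% default_fit_weights(m$age_years)
  if (length(w) != n || any(w <= 0)) {
    qeps_validation_error("weights must be positive, one per measurement")
  }

  mu <- setNames(priors$mu_log, priors$param)[PARAM_KEYS]
  sig <- setNames(priors$sigma_log, priors$param)[PARAM_KEYS]
  sw <- sqrt(w)
  resfun <- function(logb) {
    p <- exp(logb)
    names(p) <- PARAM_KEYS
    pred <- qeps_total(p, constants, m$age_years)
    c(sw * (m$height_cm - pred), sqrt(lambda) * (logb - mu) / sig)
  }

  starts <- list(mu,
                 replace(mu, 5, mu[5] + 0.5 * sig[5]),
                 replace(mu, 5, mu[5] - 0.5 * sig[5]))
  best <- NULL
  for (s0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s0, fn = resfun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    conv <- fit$info %in% 1:3
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && fit$deviance < best$fit$deviance)) {
      best <- list(fit = fit, conv = conv)
    }
  }
  if (is.null(best) || !best$conv) {
    qeps_validation_error(sprintf(
      "subject %s: optimizer failed to converge from any start", record$subject_id))
  }

  logpar <- best$fit$par
  J <- num_jacobian(resfun, logpar)
  r <- resfun(logpar)
  rss_data <- sum(r[seq_len(n)]^2)
  sigma2 <- rss_data / (n - 6)
  JtJ <- crossprod(J)
  cov <- tryCatch(sigma2 * chol2inv(chol(JtJ)),
                  error = function(e) sigma2 * solve(JtJ + diag(1e-8, 6)))
  dimnames(cov) <- list(PARAM_KEYS, PARAM_KEYS)

  params <- validate_params(structure(exp(logpar), class = "qeps_params"))
  structure(list(
    params = params, constants = constants,
    logpar = setNames(logpar, PARAM_KEYS), cov = cov,
    residual_sd = sqrt(sigma2), n_points = n,
    converged = TRUE, penalty_used = lambda,
    residuals = r[seq_len(n)] / sw, weights = w,
    subject_id = record$subject_id, sex = record$sex,
    record = record, seed = as.integer(seed)
  ), class = "qeps_fit")
}

#' @export
print.qeps_fit <- function(x, ...) {
  cat(sprintf("QEPS fit for %s (%s): %d points, residual SD %.3f cm\n",
              x$subject_id, x$sex, x$n_points, x$residual_sd))
  print(round(unclass(x$params), 3))
  invisible(x)
}

#' Parametric-bootstrap confidence intervals for all landmark variables
#'
#' Draws log-parameter vectors from the fit's multivariate-t sampling
#' distribution (location the fitted log parameters, scale their asymptotic
#' covariance, `n_points - 6` degrees of freedom — with ~15-25 measurements
#' per child the residual variance is itself estimated, and plain normal
#' draws give intervals about 7% too narrow). Near-singular covariances are
#' ridge-repaired by adding 1e-8 to the diagonal, and flagged. The full
#' pubertal summary is recomputed for each draw and percentile 2.5/97.5
#' intervals reported. Draws in which a
#' variable is undefined (e.g. a `no_spurt` draw) are counted; a variable
#' undefined in more than half the draws has its CI marked unavailable.
#' Intervals are widened, if needed, to contain the point estimate.
#'
#' @param fit a `qeps_fit`.
#' @param n_draws number of bootstrap draws (default 200).
#' @param seed integer seed.
#' @param window landmark search window, as in [t_landmarks()].
#' @return A data frame of class `qeps_cis`: `variable`, `estimate`,
#'   `lower95`, `upper95`, `n_defined`, `unavailable`; attribute
#'   `cov_repaired`.
#' @export
landmark_cis <- function(fit, n_draws = 200, seed = 1L, window = c(3, 25)) {
  if (!inherits(fit, "qeps_fit") || !isTRUE(fit$converged)) {
    qeps_validation_error("landmark_cis needs a converged qeps_fit")
  }
  cov <- fit$cov
  repaired <- FALSE
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) {
    cov <- cov + diag(1e-8, 6)
    repaired <- TRUE
  }
  set.seed(seed)
  df <- max(fit$n_points - 6L, 3L)
  scale_t <- sqrt(stats::rchisq(n_draws, df) / df)
  draws <- MASS::mvrnorm(n_draws, mu = rep(0, 6), Sigma = cov) / scale_t
  draws <- sweep(draws, 2, fit$logpar, "+")

  mat <- matrix(NA_real_, n_draws, length(SUMMARY_VARS),
                dimnames = list(NULL, SUMMARY_VARS))
  for (b in seq_len(n_draws)) {
    p <- structure(exp(draws[b, ]), class = "qeps_params")
    s <- tryCatch(pubertal_summary(p, fit$constants, window),
                  error = function(e) NULL)
    if (!is.null(s)) mat[b, ] <- summary_to_vector(s)
  }

  est <- summary_to_vector(pubertal_summary(fit$params, fit$constants, window))
  rows <- lapply(SUMMARY_VARS, function(v) {
    x <- mat[, v]
    ndef <- sum(is.finite(x))
    if (ndef < n_draws / 2) {
      data.frame(variable = v, estimate = est[[v]],
                 lower95 = NA_real_, upper95 = NA_real_,
                 n_defined = ndef, unavailable = TRUE,
                 stringsAsFactors = FALSE)
    } else {
      qs <- quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
      lo <- min(qs[1], est[[v]], na.rm = TRUE)
      hi <- max(qs[2], est[[v]], na.rm = TRUE)
      data.frame(variable = v, estimate = est[[v]],
                 lower95 = lo, upper95 = hi,
                 n_defined = ndef, unavailable = FALSE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("qeps_cis", "data.frame"), cov_repaired = repaired)
}

#' Empirical age at peak height velocity from raw measurements
#'
#' The classical chart-based estimate: over consecutive measurement pairs
#' with ages above `min_age` (default 8 years, excluding infancy
#' increments), compute the yearly height increment and return the midpoint
#' age of the pair with the greatest increment; ties break to the earliest
#' pair. A non-increasing series is flagged `degenerate`; fewer than two
#' usable measurements gives `NA` with flag `insufficient_data`.
#'
#' @param record a [growth_record()].
#' @param min_age lower age bound in years.
#' @return List with `age_years` and `flag` (`NA_character_` when clean).
#' @export
empirical_phv <- function(record, min_age = 8) {
  m <- record$measurements
  m <- m[m$age_years > min_age, , drop = FALSE]
  if (nrow(m) < 2) {
    return(list(age_years = NA_real_, flag = "insufficient_data"))
  }
  a <- m$age_years; h <- m$height_cm
  inc <- diff(h) / diff(a)
  k <- which.max(inc)  # which.max takes the earliest maximum
  list(age_years = (a[k] + a[k + 1]) / 2,
       flag = if (max(inc) <= 0) "degenerate" else NA_character_)
}

#' Fit a whole cohort
#'
#' Convenience wrapper applying [fit_individual()] to each subject of a
#' cohort or record list; failures are collected, not fatal.
#'
#' @param x a `qeps_cohort` or list of `qeps_record`s.
#' @param ... passed to [fit_individual()].
#' @return List of `qeps_fit` objects; attribute `failures` is a data frame
#'   of subject ids and error messages for subjects that could not be fitted.
#' @export
fit_cohort <- function(x, ...) {
  records <- if (inherits(x, "qeps_cohort")) lapply(x, `[[`, "record") else x
  fits <- list()
  fails <- list()
  for (r in records) {
    f <- tryCatch(fit_individual(r, ...), error = function(e) e)
    if (inherits(f, "error")) {
      fails[[length(fails) + 1L]] <- data.frame(
        subject_id = r$subject_id, message = conditionMessage(f),
        stringsAsFactors = FALSE)
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  structure(fits, failures = if (length(fails)) do.call(rbind, fails)
            else data.frame(subject_id = character(0), message = character(0)))
}
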
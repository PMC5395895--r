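# MathSelect: a composite curve-quality index calibrated as a reference-
# cohort exceedance probability. The nine quality variables cover the three
# facets a growth-curve audit looks at: fit error, precision of the derived
# landmarks, and data coverage. The published variable list is not public;
# this is a documented reimplementation with the same calibration semantics
# (the score is the expected fraction of an acceptable reference cohort
# whose fitted curves are of higher quality).

QC_VARS <- c("rmse_cm", "max_abs_studentized_residual",
             "ci_width_AgeP50_y", "ci_width_Pmax_cm", "rel_ci_width_Tmax",
             "n_measurements", "n_epochs_covered", "max_gap_years",
             "abs_diff_AgeP50_vs_empirical_phv_y")

# Variables where larger raw values mean BETTER quality get negated before
# ranking so that, oriented, larger always means worse.
QC_NEGATE <- c("n_measurements", "n_epochs_covered")

# Residuals scaled for outlier screening. The scale is robust (1.4826 * MAD
# of the weighted residuals): an RSS-based scale absorbs the very outlier
# being screened for (with ~20 points and 6 parameters a single gross error
# cannot exceed a studentized value of 4 under the naive scale).
studentized_residuals <- function(fit) {
  r <- fit$residuals * sqrt(fit$weights)
  s <- max(stats::mad(r, center = 0), 1e-8)
  r / s
}

# The eight study epochs (years): birth, infancy, toddler, child, school,
# juvenile, adolescent, adulthood.
EPOCH_BREAKS <- c(-0.1, 1e-9, 0.75, 3.5, 6, 9, 12, 16, 30)

count_epochs <- function(ages) {
  bins <- cut(ages, breaks = EPOCH_BREAKS, right = FALSE)
  covered <- tabulate(bins, nbins = 8) > 0
  # infancy epoch requires two or more measurements
  covered[2] <- sum(as.integer(bins) == 2L, na.rm = TRUE) >= 2
  sum(covered)
}

#' Nine per-subject quality variables
#'
#' Computes the scalars MathSelect combines: root-mean-square fit error,
#' the largest absolute studentized residual, the CI widths of AgeP50 and
#' Pmax, the relative CI width of modelled adult height, the number of
#' measurements, the number of the eight study epochs covered, the largest
#' age gap between consecutive measurements, and the absolute disagreement
#' between AgeP50 and the empirical (chart-style) PHV age. When CIs are
#' missing the two CI-width variables are `NA` and flagged; [mathselect()]
#' ranks them as worst.
#'
#' @param fit a converged `qeps_fit`.
#' @param record the subject's [growth_record()] (default: the one stored in
#'   the fit).
#' @param cis optional `qeps_cis` from [landmark_cis()].
#' @return Named list of class `qeps_qc` with the nine variables and a
#'   `flags` character vector.
#' @export
qc_variables <- function(fit, record = fit$record, cis = NULL) {
  if (!inherits(fit, "qeps_fit") || !isTRUE(fit$converged)) {
    qeps_validation_error("qc_variables needs a converged qeps_fit")
  }
  m <- record$measurements
  res <- fit$residuals
  stud <- studentized_residuals(fit)
  flags <- character(0)

  ci_agep50 <- ci_pmax <- rel_ci_tmax <- NA_real_
  if (is.null(cis)) {
    flags <- c(flags, "cis_missing")
  } else {
    wid <- function(v) {
      row <- cis[cis$variable == v, ]
      if (nrow(row) != 1 || isTRUE(row$unavailable)) NA_real_
      else row$upper95 - row$lower95
    }
    ci_agep50 <- wid("AgeP50")
    ci_pmax <- wid("Pmax")
    tw <- wid("Tmax")
    est <- cis$estimate[cis$variable == "Tmax"]
    rel_ci_tmax <- if (is.na(tw)) NA_real_ else tw / est
    if (anyNA(c(ci_agep50, ci_pmax, rel_ci_tmax))) flags <- c(flags, "ci_unavailable")
  }

  summ <- pubertal_summary(fit$params, fit$constants)
  ephv <- empirical_phv(record)
  dphv <- abs(summ$AgeP50 - ephv$age_years)

  structure(list(
    rmse_cm = sqrt(mean(res^2)),
    max_abs_studentized_residual = max(abs(stud)),
    ci_width_AgeP50_y = ci_agep50,
    ci_width_Pmax_cm = ci_pmax,
    rel_ci_width_Tmax = rel_ci_tmax,
    n_measurements = nrow(m),
    n_epochs_covered = count_epochs(m$age_years),
    max_gap_years = max(diff(sort(m$age_years))),
    abs_diff_AgeP50_vs_empirical_phv_y = if (is.finite(dphv)) dphv else NA_real_,
    flags = flags
  ), class = "qeps_qc")
}

qc_to_vector <- function(qc) {
  vapply(QC_VARS, function(v) as.numeric(qc[[v]] %||% NA_real_), numeric(1))
}

orient_qc <- function(vec) {
  vec[QC_NEGATE] <- -vec[QC_NEGATE]
  vec
}

#' Build the MathSelect reference distribution
#'
#' Stores the empirical distribution (sorted oriented values) of each of
#' the nine quality variables over a reference cohort of acceptable curves,
#' together with the combined quality index of every reference member, so
#' new subjects can be scored as exceedance probabilities.
#'
#' @param cohort_qc list of `qeps_qc` objects (>= 50).
#' @return Object of class `qeps_quality_reference`.
#' @export
build_quality_reference <- function(cohort_qc) {
  if (length(cohort_qc) < 50) {
    qeps_validation_error("quality reference needs >= 50 cohort members")
  }
  mat <- t(vapply(cohort_qc, function(q) orient_qc(qc_to_vector(q)),
                  numeric(length(QC_VARS))))
  colnames(mat) <- QC_VARS
  sorted <- lapply(as.data.frame(mat), function(col) sort(col[is.finite(col)]))
  ref <- structure(list(sorted = sorted, n = nrow(mat),
                        version = as.character(packageVersion("qepsgrowth"))),
                   class = "qeps_quality_reference")
  ref$combined <- apply(mat, 1, function(v) combined_index(v, ref))
  ref
}

# Fraction of reference members strictly better (smaller oriented value)
# than the subject on one variable; NA ranks as worst (1).
variable_rank <- function(value, sorted_ref) {
  if (!is.finite(value)) return(1)
  findInterval(value, sorted_ref, left.open = TRUE) / length(sorted_ref)
}

combined_index <- function(oriented_vec, reference) {
  ranks <- vapply(QC_VARS, function(v)
    variable_rank(oriented_vec[[v]], reference$sorted[[v]]), numeric(1))
  mean(ranks)
}

#' MathSelect score for one subject
#'
#' Per-variable rank = fraction of the reference strictly better than the
#' subject; combined index = mean of the nine ranks; the MathSelect value is
#' the fraction of reference members whose combined index is strictly better
#' (smaller) — i.e. the expected share of acceptable reference curves of
#' higher quality than this one. 0 means better than the whole reference,
#' 1 worse than all of it. Thresholding (keep subjects with score < tau) is
#' the caller's choice; the package defaults are 0.975 and 0.68.
#'
#' @param qc a `qeps_qc` for the subject.
#' @param reference a `qeps_quality_reference`.
#' @return Object of class `qeps_quality_score`: `mathselect`,
#'   `per_variable_ranks` (named, nine), `combined_index`, `flags`.
#' @export
mathselect <- function(qc, reference) {
  if (!inherits(reference, "qeps_quality_reference")) {
    qeps_validation_error("reference must come from build_quality_reference()")
  }
  vec <- orient_qc(qc_to_vector(qc))
  if (!all(QC_VARS %in% names(vec))) {
    qeps_validation_error("qc variables do not match the reference schema")
  }
  ranks <- vapply(QC_VARS, function(v)
    variable_rank(vec[[v]], reference$sorted[[v]]), numeric(1))
  ci <- mean(ranks)
  score <- mean(reference$combined < ci)
  structure(list(mathselect = score, per_variable_ranks = ranks,
                 combined_index = ci, flags = qc$flags),
            class = "qeps_quality_score")
}

#' Curve-level quality flags
#'
#' The audit rules applied to each fitted curve:
#' * `phv_mismatch` — |AgeP50 - empirical PHV age| strictly greater than
#'   0.66 years;
#' * `outlier_suspected` — any |studentized residual| above the cutoff
#'   (default 4);
#' * `adult_height_not_reached` — fitted total velocity above 1 cm/year at
#'   the last measurement age;
#' * `pmax_indistinguishable` — Pmax below 50% of the width of its 95% CI.
#'
#' @param fit a `qeps_fit`.
#' @param summary its [pubertal_summary()].
#' @param empirical_phv_age empirical PHV age in years (NA skips the rule).
#' @param cis optional `qeps_cis` (needed for the Pmax rule).
#' @param phv_agreement_years,outlier_cutoff,adult_velocity_cm_yr rule
#'   constants (defaults 0.66 y, 4, 1 cm/yr).
#' @return Character vector of flag tokens (possibly empty).
#' @export
flag_curve <- function(fit, summary, empirical_phv_age = NA_real_, cis = NULL,
                       phv_agreement_years = 0.66, outlier_cutoff = 4,
                       adult_velocity_cm_yr = 1) {
  flags <- character(0)
  if (is.finite(empirical_phv_age) && is.finite(summary$AgeP50) &&
      abs(summary$AgeP50 - empirical_phv_age) - phv_agreement_years > 1e-9) {
    # strictly MORE than the agreement threshold (float-guarded)
    flags <- c(flags, "phv_mismatch")
  }
  stud <- studentized_residuals(fit)
  if (any(abs(stud) > outlier_cutoff)) flags <- c(flags, "outlier_suspected")
  last_age <- max(fit$record$measurements$age_years)
  if (qeps_velocity(fit$params, fit$constants, last_age) > adult_velocity_cm_yr) {
    flags <- c(flags, "adult_height_not_reached")
  }
  if (!is.null(cis)) {
    row <- cis[cis$variable == "Pmax", ]
    if (nrow(row) == 1 && !isTRUE(row$unavailable)) {
      width <- row$upper95 - row$lower95
      if (summary$Pmax < 0.5 * width) flags <- c(flags, "pmax_indistinguishable")
    }
  }
  flags
}

#' Persist / reload a quality reference
#'
#' Flat versioned CSV: one row per (variable, sorted value), plus the
#' precomputed combined indices under the pseudo-variable
#' `.combined_index`. Values round-trip bit-exactly.
#'
#' @param reference a `qeps_quality_reference`; `path` a file path.
#' @export
write_quality_reference <- function(reference, path) {
  rows <- do.call(rbind, c(
    lapply(QC_VARS, function(v) {
      vals <- reference$sorted[[v]]
      if (!length(vals)) return(NULL)
      data.frame(variable = v, value = sprintf("%.17g", vals),
                 stringsAsFactors = FALSE)
    }),
    list(data.frame(variable = ".combined_index",
                    value = sprintf("%.17g", reference$combined),
                    stringsAsFactors = FALSE))))
  header <- sprintf("# qepsgrowth quality reference v%s n=%d",
                    reference$version, reference$n)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, "variable,value"), con)
  writeLines(sprintf("%s,%s", rows$variable, rows$value), con)
  invisible(path)
}

#' @rdname write_quality_reference
#' @export
read_quality_reference <- function(path) {
  lines <- readLines(path)
  header <- lines[1]
  n <- as.integer(sub(".* n=(\\d+)$", "\\1", header))
  version <- sub("^# qepsgrowth quality reference v(\\S+) .*$", "\\1", header)
  df <- read.csv(text = lines[-1], stringsAsFactors = FALSE,
                 colClasses = c("character", "numeric"))
  sorted <- lapply(setNames(QC_VARS, QC_VARS),
                   function(v) df$value[df$variable == v])
  structure(list(sorted = sorted, n = n, version = version,
                 combined = df$value[df$variable == ".combined_index"]),
            class = "qeps_quality_reference")
}

#' Cohort QC table
#'
#' One row per subject: the nine QC variables, the MathSelect score and the
#' flag tokens, ready to write as the QC output CSV.
#'
#' @param fits list of `qeps_fit`; `cis_list` optional parallel list of
#'   `qeps_cis`; `reference` a quality reference (when `NULL`, it is built
#'   from this cohort itself).
#' @return List with `table` (data frame) and `reference` used.
#' @export
cohort_qc <- function(fits, cis_list = NULL, reference = NULL) {
  qcs <- lapply(seq_along(fits), function(i) {
    qc_variables(fits[[i]], cis = if (is.null(cis_list)) NULL else cis_list[[i]])
  })
  if (is.null(reference)) reference <- build_quality_reference(qcs)
  rows <- lapply(seq_along(fits), function(i) {
    ms <- mathselect(qcs[[i]], reference)
    summ <- pubertal_summary(fits[[i]]$params, fits[[i]]$constants)
    ephv <- empirical_phv(fits[[i]]$record)
    fl <- flag_curve(fits[[i]], summ, ephv$age_years,
                     cis = if (is.null(cis_list)) NULL else cis_list[[i]])
    cbind(data.frame(subject_id = fits[[i]]$subject_id, stringsAsFactors = FALSE),
          as.data.frame(as.list(qc_to_vector(qcs[[i]]))),
          data.frame(mathselect = ms$mathselect,
                     flags = paste(unique(c(qcs[[i]]$flags, fl)), collapse = ";"),
                     stringsAsFactors = FALSE))
  })
  list(table = do.call(rbind, rows), reference = reference)
}
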
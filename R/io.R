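#' Construct a growth record for one subject
#'
#' @param subject_id opaque identifier.
#' @param sex `"F"` or `"M"`.
#' @param age_years,height_cm equal-length numeric vectors; ages in decimal
#'   years since birth (must lie in \[-0.1, 30\]), heights in cm (must lie in
#'   (30, 230)). Measurements are stored sorted by age; duplicate ages are
#'   allowed.
#' @return An object of class `qeps_record`.
#' @export
growth_record <- function(subject_id, sex, age_years, height_cm) {
  if (!sex %in% c("F", "M")) qeps_validation_error("sex must be 'F' or 'M'")
  if (length(age_years) != length(height_cm)) {
    qeps_validation_error("age_years and height_cm must have equal length")
  }
  if (!all(is.finite(age_years)) || !all(is.finite(height_cm))) {
    qeps_validation_error("measurements must be finite")
  }
  if (any(age_years < -0.1 | age_years > 30)) {
    qeps_validation_error("ages must lie in [-0.1, 30] years")
  }
  if (any(height_cm <= 30 | height_cm >= 230)) {
    qeps_validation_error("heights must lie in (30, 230) cm")
  }
  o <- order(age_years)
  structure(list(subject_id = as.character(subject_id), sex = sex,
                 measurements = data.frame(age_years = age_years[o],
                                           height_cm = height_cm[o])),
            class = "qeps_record")
}

#' @export
print.qeps_record <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("Growth record %s (sex %s): %d measurements, ages %.2f-%.2f y\n",
              x$subject_id, x$sex, nrow(m), min(m$age_years), max(m$age_years)))
  invisible(x)
}

#' Read growth records from a measurements CSV
#'
#' Expects a UTF-8 CSV with header `subject_id,sex,age_years,height_cm`.
#' Malformed rows (unparsable numbers, invalid sex, out-of-range values) are
#' collected into a rejects report attached as attribute `"rejects"` (a data
#' frame with the 1-based data line number and a reason) — they are reported,
#' never silently dropped.
#'
#' @param path file path.
#' @return A list of [growth_record()] objects, one per subject (rows grouped
#'   by subject and sorted by age), with attribute `rejects`.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) qeps_validation_error(sprintf("file not found: %s", path))
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  needed <- c("subject_id", "sex", "age_years", "height_cm")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    qeps_validation_error(paste("missing column(s):",
                                paste(missing_cols, collapse = ", ")))
  }
  if (nrow(raw) == 0) qeps_validation_error("empty measurements file")

  age <- suppressWarnings(as.numeric(raw$age_years))
  ht <- suppressWarnings(as.numeric(raw$height_cm))
  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(age)] <- "unparsable age_years"
  reason[is.na(ht) & is.na(reason)] <- "unparsable height_cm"
  reason[!raw$sex %in% c("F", "M") & is.na(reason)] <- "sex must be F or M"
  ok <- is.na(reason)
  reason[ok & (age < -0.1 | age > 30)] <- "age outside [-0.1, 30]"
  ok <- is.na(reason)
  reason[ok & (ht <= 30 | ht >= 230)] <- "height outside (30, 230)"
  ok <- is.na(reason)

  rejects <- data.frame(line = which(!ok), reason = reason[!ok],
                        stringsAsFactors = FALSE)
  keep <- raw[ok, , drop = FALSE]
  age <- age[ok]; ht <- ht[ok]
  records <- lapply(split(seq_len(nrow(keep)), keep$subject_id), function(idx) {
    growth_record(keep$subject_id[idx[1]], keep$sex[idx[1]],
                  age_years = age[idx], height_cm = ht[idx])
  })
  # preserve first-appearance order of subjects
  first <- vapply(split(seq_len(nrow(keep)), keep$subject_id), min, numeric(1))
  records <- records[order(first)]
  structure(unname(records), rejects = rejects)
}

#' Write growth records to a measurements CSV
#'
#' Inverse of [read_measurements()]; ages are written with 4 decimals,
#' heights with 2 (measurement resolution).
#'
#' @param records list of `qeps_record` objects (or a `qeps_cohort`).
#' @param path output path.
#' @export
write_measurements <- function(records, path) {
  if (inherits(records, "qeps_cohort")) {
    records <- lapply(records, `[[`, "record")
  }
  rows <- lapply(records, function(r) {
    data.frame(subject_id = r$subject_id, sex = r$sex,
               age_years = sprintf("%.4f", r$measurements$age_years),
               height_cm = sprintf("%.2f", r$measurements$height_cm),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize parameters and shape constants to a flat key-value block
#'
#' Keys are exactly `t0, U, sP, xS, wS, adult_eval_age, hQ, hE, thetaE, hP,
#' thetaP, hS` (YAML dialect). The sex of the constants travels alongside.
#'
#' @param params a `qeps_params`; `constants` a `qeps_constants`.
#' @param path output path; for `read_model_config` the input path.
#' @return `read_model_config` returns `list(params, constants)`.
#' @export
write_model_config <- function(params, constants, path) {
  params <- as_qeps_params(params)
  block <- c(list(sex = constants$sex),
             setNames(lapply(CONSTANT_KEYS, function(k) constants[[k]]), CONSTANT_KEYS),
             as.list(unclass(params)))
  yaml::write_yaml(block, path, precision = 17)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  block <- yaml::read_yaml(path)
  const <- do.call(qeps_constants,
                   c(list(sex = block$sex),
                     block[intersect(CONSTANT_KEYS, names(block))]))
  params <- as_qeps_params(unlist(block[PARAM_KEYS]))
  list(params = params, constants = const)
}

#' Run configuration for pipeline commands
#'
#' Collects every tunable the pipeline uses: penalty weight, bootstrap
#' draws, MathSelect thresholds (0.975 and 0.68), the curve-check constants
#' (0.66-year mid-puberty agreement rule, studentized-residual cutoff 4,
#' 1 cm/year adult-height velocity rule) and the noise model. Serializes to
#' YAML; [config_hash()] gives a digest echoed into run manifests.
#'
#' @param ... named overrides of the defaults.
#' @return A named list of class `qeps_config`.
#' @export
qeps_config <- function(...) {
  cfg <- list(
    penalty_weight = NA_real_,      # NA = default 0.01 * n_points
    bootstrap_draws = 200L,
    mathselect_thresholds = c(0.975, 0.68),
    phv_agreement_years = 0.66,
    outlier_cutoff = 4,
    adult_velocity_cm_yr = 1,
    sd_infant = 0.45,
    sd_child = 0.27,
    density = "standard",
    search_window = c(3, 25)
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    qeps_validation_error(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  pos <- c("bootstrap_draws", "phv_agreement_years", "outlier_cutoff",
           "adult_velocity_cm_yr", "sd_infant", "sd_child")
  for (k in pos) {
    if (any(!is.na(cfg[[k]]) & cfg[[k]] <= 0)) {
      qeps_validation_error(sprintf("config key %s must be positive", k))
    }
  }
  structure(cfg, class = "qeps_config")
}

#' @rdname qeps_config
#' @param cfg a `qeps_config`; `path` a file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 17)
  invisible(path)
}

#' @rdname qeps_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(qeps_config, raw)
}

#' @rdname qeps_config
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(cfg), tmp, precision = 17)
  unname(tools::md5sum(tmp))
}
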
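# Tempo-adjusted referencing: landmark means/SDs per sex, plus mean/SD
# height bands for T, P and QES on a relative-age grid aligned to each
# subject's pubertal onset (AgeP5 subtracted), so SD-scores correct for
# pubertal timing instead of mixing early and late developers.

REF_GRID <- seq(-6, 10, by = 0.1)
CURVE_COMPONENTS <- c("T", "P", "QES")

#' Build per-sex landmark and tempo-aligned curve references
#'
#' Landmark reference: mean and SD of every pubertal-summary variable per
#' sex. Curve reference: each subject's fitted T, P and QES heights are
#' evaluated at `relative age + subject's AgeP5` on the grid -6..+10 years
#' (step 0.1) and pointwise means/SDs taken per sex. Subjects flagged
#' `no_spurt` have no AgeP5 and are excluded from the curve bands (their
#' count is kept in metadata).
#'
#' @param cohort list of subjects, each a list with elements `fit`
#'   (a `qeps_fit`) and `summary` (its [pubertal_summary()]).
#' @param min_n minimum subjects per sex with detectable spurts (default 50).
#' @return Object of class `qeps_reference` with elements `landmarks`
#'   (data frame: sex, variable, mean, sd, n), `curves` (data frame: sex,
#'   component, rel_age, mean, sd, n), `meta`.
#' @export
build_reference <- function(cohort, min_n = 50) {
  sexes <- vapply(cohort, function(s) s$fit$sex, character(1))
  has_spurt <- vapply(cohort, function(s) is.finite(s$summary$AgeP5), logical(1))
  for (sx in unique(sexes)) {
    if (sum(sexes == sx & has_spurt) < min_n) {
      qeps_validation_error(sprintf(
        "need >= %d subjects with detectable spurts per sex (sex %s has %d)",
        min_n, sx, sum(sexes == sx & has_spurt)))
    }
  }

  land <- do.call(rbind, lapply(unique(sexes), function(sx) {
    mat <- t(vapply(cohort[sexes == sx],
                    function(s) summary_to_vector(s$summary),
                    numeric(length(SUMMARY_VARS))))
    do.call(rbind, lapply(SUMMARY_VARS, function(v) {
      x <- mat[, v]; x <- x[is.finite(x)]
      data.frame(sex = sx, variable = v, mean = mean(x), sd = sd(x),
                 n = length(x), stringsAsFactors = FALSE)
    }))
  }))
  # A cohort of identical subjects has no variation anywhere and cannot
  # standardize anything. Individual zero-variance variables (a design with
  # a parameter held fixed) are kept; their SDS is undefined downstream.
  if (all(!is.finite(land$sd) | land$sd == 0)) {
    qeps_validation_error("reference cohort has zero variance throughout; need real variation")
  }

  curves <- do.call(rbind, lapply(unique(sexes), function(sx) {
    idx <- which(sexes == sx & has_spurt)
    arr <- lapply(idx, function(i) {
      s <- cohort[[i]]
      ages <- REF_GRID + s$summary$AgeP5
      cv <- qeps_evaluate(s$fit$params, s$fit$constants, ages, order = 0)
      cbind(T = cv$T, P = cv$P, QES = cv$QES)
    })
    do.call(rbind, lapply(CURVE_COMPONENTS, function(comp) {
      m <- vapply(arr, function(a) a[, comp], numeric(length(REF_GRID)))
      data.frame(sex = sx, component = comp, rel_age = REF_GRID,
                 mean = rowMeans(m), sd = apply(m, 1, sd),
                 n = length(idx), stringsAsFactors = FALSE)
    }))
  }))
  if (all(curves$sd == 0)) {
    qeps_validation_error("curve reference has zero pointwise variance; need real variation")
  }

  structure(list(
    landmarks = land, curves = curves,
    meta = list(version = as.character(packageVersion("qepsgrowth")),
                n_total = length(cohort),
                n_no_spurt = sum(!has_spurt))
  ), class = "qeps_reference")
}

#' SD-scores of landmark estimates against a reference
#'
#' `SDS = (value - mean) / SD`, per sex. Variables undefined in the summary
#' yield `NA` scores, listed in the `undefined` attribute.
#'
#' @param summary a [pubertal_summary()].
#' @param reference a `qeps_reference`.
#' @param sex `"F"` or `"M"`.
#' @param variables which variables to score (default: all in the reference).
#' @return Named numeric vector of SD-scores.
#' @export
sds_estimates <- function(summary, reference, sex, variables = NULL) {
  ref <- reference$landmarks[reference$landmarks$sex == sex, ]
  if (nrow(ref) == 0) qeps_validation_error(sprintf("reference has no sex %s", sex))
  variables <- variables %||% ref$variable
  unknown <- setdiff(variables, ref$variable)
  if (length(unknown)) {
    qeps_validation_error(paste("variable(s) not in reference:",
                                paste(unknown, collapse = ", ")))
  }
  vals <- summary_to_vector(summary)[variables]
  mu <- setNames(ref$mean, ref$variable)[variables]
  sdv <- setNames(ref$sd, ref$variable)[variables]
  out <- (vals - mu) / sdv
  attr(out, "undefined") <- variables[!is.finite(vals)]
  out
}

#' Tempo-aligned SD-score curves for one subject
#'
#' Evaluates the subject's fitted T, P and QES heights at the reference's
#' relative-age grid shifted to the subject's own AgeP5, and standardizes
#' pointwise against the per-sex curve bands. Grid points that would fall
#' before the growth origin are truncated and flagged.
#'
#' @param fit a `qeps_fit`; `summary` its [pubertal_summary()] (must have a
#'   defined AgeP5).
#' @param reference a `qeps_reference`; `sex` `"F"` or `"M"`.
#' @return Data frame `rel_age`, `component`, `value_cm`, `sds`; attribute
#'   `truncated` (logical).
#' @export
tempo_aligned_curves <- function(fit, summary, reference, sex) {
  if (!is.finite(summary$AgeP5)) {
    qeps_validation_error("subject has no detectable spurt: AgeP5 undefined")
  }
  ref <- reference$curves[reference$curves$sex == sex, ]
  if (nrow(ref) == 0) qeps_validation_error(sprintf("reference has no sex %s", sex))
  ages <- REF_GRID + summary$AgeP5
  keep <- ages >= fit$constants$t0
  truncated <- any(!keep)
  cv <- qeps_evaluate(fit$params, fit$constants, ages[keep], order = 0)
  out <- do.call(rbind, lapply(CURVE_COMPONENTS, function(comp) {
    band <- ref[ref$component == comp, ]
    stopifnot(nrow(band) == length(REF_GRID))
    vals <- cv[[comp]]
    data.frame(rel_age = REF_GRID[keep], component = comp, value_cm = vals,
               sds = (vals - band$mean[keep]) / band$sd[keep],
               stringsAsFactors = FALSE)
  }))
  structure(out, truncated = truncated)
}

#' Persist / reload a tempo-adjusted reference
#'
#' Versioned flat CSV, bit-exact round trip: landmark rows
#' `(sex, "landmark", variable, NA, mean, sd, n)` and curve rows
#' `(sex, component, NA, rel_age, mean, sd, n)` behind a metadata header.
#'
#' @param reference a `qeps_reference`; `path` a file path.
#' @export
write_reference <- function(reference, path) {
  g17 <- function(x) sprintf("%.17g", x)
  l <- reference$landmarks
  c2 <- reference$curves
  rows <- c(
    sprintf("%s,landmark,%s,,%s,%s,%d", l$sex, l$variable, g17(l$mean), g17(l$sd), l$n),
    sprintf("%s,%s,,%s,%s,%s,%d", c2$sex, c2$component, g17(c2$rel_age),
            g17(c2$mean), g17(c2$sd), c2$n))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# qepsgrowth reference v%s n_total=%d n_no_spurt=%d",
                       reference$meta$version, reference$meta$n_total,
                       reference$meta$n_no_spurt),
               "sex,kind,variable,rel_age,mean,sd,n", rows), con)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  lines <- readLines(path)
  meta_line <- lines[1]
  df <- read.csv(text = lines[-1], stringsAsFactors = FALSE,
                 colClasses = c("character", "character", "character",
                                "numeric", "numeric", "numeric", "integer"))
  land <- df[df$kind == "landmark", ]
  curves <- df[df$kind != "landmark", ]
  structure(list(
    landmarks = data.frame(sex = land$sex, variable = land$variable,
                           mean = land$mean, sd = land$sd, n = land$n,
                           stringsAsFactors = FALSE),
    curves = data.frame(sex = curves$sex, component = curves$kind,
                        rel_age = curves$rel_age, mean = curves$mean,
                        sd = curves$sd, n = curves$n, stringsAsFactors = FALSE),
    meta = list(
      version = sub("^# qepsgrowth reference v(\\S+) .*$", "\\1", meta_line),
      n_total = as.integer(sub(".* n_total=(\\d+).*", "\\1", meta_line)),
      n_no_spurt = as.integer(sub(".* n_no_spurt=(\\d+).*", "\\1", meta_line)))
  ), class = "qeps_reference")
}
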
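# Reference cohorts here are built from true parameter draws wrapped in
# minimal fit-like objects: build_reference only consults params/constants/
# sex, so no optimizer runs are needed.
make_ref_cohort <- function(n_per_sex = 60, seed = 101, perturb = NULL) {
  set.seed(seed)
  out <- list()
  for (sx in c("F", "M")) {
    const <- qeps_constants(sx)
    pm <- default_population_model(sx)
    pars <- qepsgrowth:::draw_parameters(pm, n_per_sex)
    for (i in seq_len(n_per_sex)) {
      p <- qepsgrowth:::as_qeps_params(pars[i, ])
      if (!is.null(perturb)) p <- perturb(p)
      out[[length(out) + 1L]] <- list(
        fit = fitlike(p, const, sprintf("%s%03d", sx, i)),
        summary = pubertal_summary(p, const))
    }
  }
  out
}

test_that("reference captures the generator's landmark moments", {
  coh <- make_ref_cohort(250, seed = 102)
  ref <- build_reference(coh)
  row <- ref$landmarks[ref$landmarks$sex == "F" &
                         ref$landmarks$variable == "AgeP50", ]
  expect_lt(abs(row$mean - 12.09), 2 * 0.95 / sqrt(row$n))
  expect_gt(row$sd, 0.8); expect_lt(row$sd, 1.1)
  expect_true(all(ref$curves$sd > 0))
  expect_true(all(diff(ref$curves$rel_age[ref$curves$sex == "F" &
                                            ref$curves$component == "T"]) > 0))
})

test_that("degenerate reference cohorts are rejected", {
  coh <- make_ref_cohort(20, seed = 103)
  expect_error(build_reference(coh), class = "qeps_validation_error")
  # identical subjects: zero variance must error rather than divide by zero
  p <- girl_params(); const <- qeps_constants("F")
  same <- lapply(1:60, function(i)
    list(fit = fitlike(p, const), summary = pubertal_summary(p, const)))
  expect_error(build_reference(same, min_n = 50),
               class = "qeps_validation_error")
})

test_that("SD-scores are the standardization identity, invertible exactly", {
  coh <- make_ref_cohort(60, seed = 104)
  ref <- build_reference(coh)
  s <- coh[[5]]$summary
  sds <- sds_estimates(s, ref, "F")
  land <- ref$landmarks[ref$landmarks$sex == "F", ]
  mu <- setNames(land$mean, land$variable)
  sdv <- setNames(land$sd, land$variable)
  vals <- qepsgrowth:::summary_to_vector(s)
  ok <- is.finite(vals)
  # value = mean + SDS * SD to machine precision
  expect_equal(mu[ok] + as.numeric(sds)[ok] * sdv[ok], vals[ok],
               tolerance = 1e-12)
  # canonical anchor points
  s2 <- s; s2$AgeP50 <- mu[["AgeP50"]]
  expect_equal(as.numeric(sds_estimates(s2, ref, "F", "AgeP50")), 0)
  s2$AgeP50 <- mu[["AgeP50"]] + 2 * sdv[["AgeP50"]]
  expect_equal(as.numeric(sds_estimates(s2, ref, "F", "AgeP50")), 2)
  expect_error(sds_estimates(s, ref, "F", "NotAVariable"),
               class = "qeps_validation_error")
})

test_that("a girl at +2 SD of the timing reference scores AgeP50 SDS about 2", {
  # reference moments from the published tables: mean 12.09, SD 0.95
  expect_equal(round((14.0 - 12.09) / 0.95, 2), 2.01)
})

test_that("reference serialization round-trips bit-exactly", {
  coh <- make_ref_cohort(55, seed = 105)
  ref <- build_reference(coh)
  path <- tempfile(fileext = ".csv")
  write_reference(ref, path)
  ref2 <- read_reference(path)
  expect_identical(ref$landmarks$mean, ref2$landmarks$mean)
  expect_identical(ref$landmarks$sd, ref2$landmarks$sd)
  expect_identical(ref$curves$mean, ref2$curves$mean)
  expect_identical(ref$curves$sd, ref2$curves$sd)
  expect_identical(ref$meta$n_total, ref2$meta$n_total)
})

test_that("a subject matching the reference mean curve scores SDS 0 everywhere", {
  # symmetric height-scale perturbations with fixed time scales: the curve
  # bands' pointwise mean IS the mean-parameter curve (the model is linear
  # in its height scales and alignment depends only on thetaP)
  p0 <- girl_params()
  const <- qeps_constants("F")
  grid <- expand.grid(dq = seq(-2, 2, length.out = 5),
                      dp = seq(-3, 3, length.out = 5))
  coh <- lapply(seq_len(nrow(grid)), function(i) {
    p <- qeps_params(hQ = p0[["hQ"]] + grid$dq[i], hE = p0[["hE"]],
                     thetaE = p0[["thetaE"]], hP = p0[["hP"]] + grid$dp[i],
                     thetaP = p0[["thetaP"]], hS = p0[["hS"]])
    list(fit = fitlike(p, const), summary = pubertal_summary(p, const))
  })
  ref <- build_reference(coh, min_n = 25)
  mid <- coh[[13]]  # (0, 0): the mean-parameter subject
  tc <- tempo_aligned_curves(mid$fit, mid$summary, ref, "F")
  expect_lt(max(abs(tc$sds)), 0.05)
  # and a +2 SD pubertal-scale subject scores +2 on the P curve
  sd_hp <- sd(vapply(coh, function(s) s$fit$params[["hP"]], numeric(1)))
  p2 <- qeps_params(hQ = p0[["hQ"]], hE = p0[["hE"]], thetaE = p0[["thetaE"]],
                    hP = p0[["hP"]] + 2 * sd_hp, thetaP = p0[["thetaP"]],
                    hS = p0[["hS"]])
  tc2 <- tempo_aligned_curves(fitlike(p2, const),
                              pubertal_summary(p2, const), ref, "F")
  p_at5 <- tc2[tc2$component == "P" & abs(tc2$rel_age - 5) < 1e-9, ]
  expect_equal(p_at5$sds, 2, tolerance = 0.05)
})

test_that("tempo alignment removes timing variance from the P band", {
  p0 <- girl_params()
  const <- qeps_constants("F")
  set.seed(106)
  thetas <- rnorm(60, 12.74, 0.95)
  coh <- lapply(thetas, function(th) {
    p <- qeps_params(hQ = p0[["hQ"]], hE = p0[["hE"]], thetaE = p0[["thetaE"]],
                     hP = p0[["hP"]], thetaP = th, hS = p0[["hS"]])
    list(fit = fitlike(p, const), summary = pubertal_summary(p, const))
  })
  ref <- build_reference(coh, min_n = 50)
  aligned_sd <- ref$curves$sd[ref$curves$sex == "F" &
                                ref$curves$component == "P"]
  # chronological-age band over the same absolute age span
  grid <- qepsgrowth:::REF_GRID + mean(vapply(coh, function(s)
    s$summary$AgeP5, numeric(1)))
  chron <- vapply(coh, function(s)
    qeps_evaluate(s$fit$params, const, grid, order = 0)$P,
    numeric(length(grid)))
  chron_sd <- apply(chron, 1, sd)
  expect_lt(median(aligned_sd), median(chron_sd))
})

test_that("subjects without spurts are excluded from curve bands but counted", {
  coh <- make_ref_cohort(55, seed = 107)
  p0 <- qeps_params(hQ = 95, hE = 62, thetaE = 0.54, hP = 0,
                    thetaP = 12.7, hS = 6)
  const <- qeps_constants("F")
  coh[[length(coh) + 1L]] <- list(fit = fitlike(p0, const),
                                  summary = pubertal_summary(p0, const))
  ref <- build_reference(coh)
  expect_equal(ref$meta$n_no_spurt, 1)
  expect_error(tempo_aligned_curves(fitlike(p0, const),
                                    pubertal_summary(p0, const), ref, "F"),
               class = "qeps_validation_error")
})
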
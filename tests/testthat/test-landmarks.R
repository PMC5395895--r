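test_that("percentile-age inversion satisfies its defining equation", {
  set.seed(21)
  const <- qeps_constants("F")
  qs <- c(0.01, 0.05, 0.5, 0.95, 0.99)
  for (i in 1:8) {
    p <- random_params()
    ages <- vapply(qs, function(q) age_at_p_fraction(p, const, q), numeric(1))
    pvals <- qeps_evaluate(p, const, ages, order = 0)$P
    expect_true(all(abs(pvals - qs * p[["hP"]]) < 1e-8 * p[["hP"]]))
    expect_true(all(diff(ages) > 0))  # strictly increasing in q
  }
})

test_that("AgeP50 is the mid-spurt age t0 + thetaP", {
  p <- girl_params()
  const <- qeps_constants("F")
  expect_equal(age_at_p_fraction(p, const, 0.5), 12.09, tolerance = 1e-12)
  # repeatability
  expect_identical(age_at_p_fraction(p, const, 0.5),
                   age_at_p_fraction(p, const, 0.5))
})

test_that("5% percentile age agrees with an independent bisection solve", {
  p <- boy_params()
  const <- qeps_constants("M")
  f <- function(a) oracle_P(p, const, a) - 0.05 * p[["hP"]]
  root <- uniroot(f, c(5, 20), tol = 1e-12)$root
  expect_equal(age_at_p_fraction(p, const, 0.05), root, tolerance = 1e-9)
})

test_that("percentile inversion rejects degenerate input", {
  const <- qeps_constants("F")
  p0 <- qeps_params(hQ = 90, hE = 60, thetaE = 0.7, hP = 0, thetaP = 13, hS = 6)
  expect_error(age_at_p_fraction(p0, const, 0.5), class = "qeps_validation_error")
  expect_error(age_at_p_fraction(girl_params(), const, 1),
               class = "qeps_validation_error")
  expect_error(age_at_p_fraction(girl_params(), const, 0),
               class = "qeps_validation_error")
})

test_that("P-function PHV sits at 4/9 of the pubertal gain", {
  set.seed(22)
  const <- qeps_constants("M")
  for (i in 1:5) {
    p <- random_params()
    pl <- p_landmarks(p, const)
    frac <- qeps_evaluate(p, const, pl$AgeP_phv, order = 0)$P / p[["hP"]]
    expect_equal(frac, 4 / 9, tolerance = 1e-9)
    # dense-grid argmax of P velocity agrees
    grid <- seq(5, 22, by = 1e-4)
    pv <- qeps_evaluate(p, const, grid, order = 1)$P
    expect_lt(abs(grid[which.max(pv)] - pl$AgeP_phv), 1e-3)
    expect_equal(pl$AgeS0, const$t0 + p[["thetaP"]] * const$xS)
  }
})

test_that("absent spurt flags no_spurt with undefined percentile ages", {
  const <- qeps_constants("F")
  p0 <- qeps_params(hQ = 90, hE = 60, thetaE = 0.7, hP = 0, thetaP = 13, hS = 6)
  pl <- p_landmarks(p0, const)
  expect_true("no_spurt" %in% pl$flags)
  expect_true(is.na(pl$AgeP50) && is.na(pl$AgeP_phv))
  s <- pubertal_summary(p0, const)
  expect_true("no_spurt" %in% s$flags)
  expect_true(all(c("onset_undetectable", "phv_undetectable") %in% s$flags))
})

test_that("total-curve landmarks agree with dense-grid brute force", {
  set.seed(23)
  const <- qeps_constants("F")
  for (i in 1:15) {
    p <- random_params(hP_range = c(9, 25))
    tl <- t_landmarks(p, const)
    o <- oracle_t_landmarks(p, const)
    expect_lt(abs(tl$AgeT_onset - o$onset), 1e-3)
    expect_lt(abs(tl$AgeT_phv - o$phv), 1e-3)
    expect_lt(abs(tl$AgeT_end - o$end), 1e-3)
    expect_true(tl$AgeT_onset < tl$AgeT_phv && tl$AgeT_phv < tl$AgeT_end)
    # the end-of-puberty definition: velocity exactly 1 cm/yr
    expect_lt(abs(qeps_evaluate(p, const, tl$AgeT_end, order = 1)$T - 1), 1e-6)
  }
})

test_that("monotone-declining velocity flags onset and PHV undetectable", {
  const <- qeps_constants("F")
  p0 <- qeps_params(hQ = 97, hE = 62, thetaE = 0.7, hP = 0, thetaP = 12.7, hS = 6)
  tl <- t_landmarks(p0, const)
  expect_setequal(tl$flags, c("onset_undetectable", "phv_undetectable"))
  expect_true(is.finite(tl$AgeT_end))
})

test_that("interval gains decompose additively and hit the percentile fractions", {
  set.seed(24)
  const <- qeps_constants("M")
  for (i in 1:8) {
    p <- random_params()
    a0 <- runif(1, 0, 12); a1 <- a0 + runif(1, 0, 10)
    g <- interval_gains(p, const, a0, a1)
    expect_identical(g$Tgain, g$Pgain + g$QESgain)
    g0 <- interval_gains(p, const, a0, a0)
    expect_true(all(unlist(g0) == 0))
    p5 <- age_at_p_fraction(p, const, 0.05)
    p95 <- age_at_p_fraction(p, const, 0.95)
    expect_equal(interval_gains(p, const, p5, p95)$Pgain, 0.9 * p[["hP"]],
                 tolerance = 1e-9)
  }
  expect_error(interval_gains(girl_params(), qeps_constants("F"), 10, 9),
               class = "qeps_validation_error")
})

test_that("landmark ages are invariant and gains equivariant under height rescaling", {
  set.seed(25)
  const <- qeps_constants("F")
  p <- random_params(hP_range = c(9, 25))
  cfac <- 1.37
  ps <- qeps_params(hQ = cfac * p[["hQ"]], hE = cfac * p[["hE"]],
                    thetaE = p[["thetaE"]], hP = cfac * p[["hP"]],
                    thetaP = p[["thetaP"]], hS = cfac * p[["hS"]])
  s1 <- pubertal_summary(p, const)
  s2 <- pubertal_summary(ps, const)
  for (v in c("AgeP1", "AgeP5", "AgeP50", "AgeP95", "AgeP99", "AgeP_phv",
              "AgeS0", "AgeT_onset", "AgeT_phv")) {
    expect_equal(s2[[v]], s1[[v]], tolerance = 1e-7)
  }
  for (v in c("Pmax", "Tmax", "Ppubgain", "Tpubgain", "QESpubgain")) {
    expect_equal(s2[[v]], cfac * s1[[v]], tolerance = 1e-7)
  }
  # AgeT_end is NOT invariant: its 1 cm/yr threshold is absolute
  expect_gt(s2$AgeT_end, s1$AgeT_end)
})

test_that("pubertal summary is internally consistent for both sexes", {
  for (sx in c("F", "M")) {
    p <- if (sx == "F") girl_params() else boy_params()
    s <- pubertal_summary(p, qeps_constants(sx))
    expect_length(s$flags, 0)
    expect_true(s$AgeP1 < s$AgeP5 && s$AgeP5 < s$AgeP50 &&
                s$AgeP50 < s$AgeP95 && s$AgeP95 < s$AgeP99)
    expect_true(s$AgeT_onset < s$AgeT_phv && s$AgeT_phv < s$AgeT_end)
    expect_gt(s$dP5_95, 0)
    expect_gt(s$dP1_99, s$dP5_95)
    expect_equal(s$Ppubgain, 0.95 * p[["hP"]])
    expect_equal(s$Tmax, s$Emax + s$Qmax + s$Pmax - s$Smax)
    # mid-spurt splits the P5-P95 gain into two 45% halves
    pv <- qeps_evaluate(p, qeps_constants(sx),
                        c(s$AgeP5, s$AgeP50, s$AgeP95), order = 0)$P
    expect_equal((pv[2] - pv[1]) / p[["hP"]], 0.45, tolerance = 1e-9)
    expect_equal((pv[3] - pv[2]) / p[["hP"]], 0.45, tolerance = 1e-9)
  }
})

test_that("cohort landmark table carries one row per subject with flag tokens", {
  const <- qeps_constants("F")
  p0 <- qeps_params(hQ = 90, hE = 60, thetaE = 0.7, hP = 0, thetaP = 13, hS = 6)
  tab <- cohort_landmarks(list(girl_params(), p0), constants = const)
  expect_equal(nrow(tab), 2)
  expect_true(all(c("subject_id", "AgeP50", "Tmax", "flags") %in% names(tab)))
  expect_match(tab$flags[2], "no_spurt")
  expect_identical(tab$flags[1], "")
})
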
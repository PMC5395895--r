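# Shared fixtures and independent oracles for the suite. The basis oracles
# below evaluate each growth function directly from its defining formula,
# kept deliberately separate from the package's evaluator.

girl_params <- function() {
  qeps_params(hQ = 97.61, hE = 62.86, thetaE = 0.54,
              hP = 12.78, thetaP = 12.74, hS = 5.99)
}

boy_params <- function() {
  qeps_params(hQ = 104.05, hE = 65.08, thetaE = 0.58,
              hP = 17.34, thetaP = 14.45, hS = 6.04)
}

# Population-plausible random parameter draw (uses ambient RNG).
random_params <- function(hP_range = c(5, 25)) {
  qeps_params(hQ = runif(1, 80, 120), hE = runif(1, 55, 70),
              thetaE = runif(1, 0.5, 1.0), hP = runif(1, hP_range[1], hP_range[2]),
              thetaP = runif(1, 11, 16), hS = runif(1, 4, 8))
}

z50_oracle <- log(1 + sqrt(2))

oracle_E <- function(p, const, a) {
  p[["hE"]] * (1 - exp(-(a - const$t0) / p[["thetaE"]]))
}

oracle_Q <- function(p, const, a) {
  v <- pmin((a - const$t0) / const$U, 1)
  p[["hQ"]] * (2 * v - v^2)
}

oracle_P <- function(p, const, a) {
  x <- (a - const$t0) / p[["thetaP"]]
  z <- (x - 1) / const$sP + z50_oracle
  L <- 1 / (1 + exp(-z))
  p[["hP"]] * L^2
}

oracle_S <- function(p, const, a) {
  x <- (a - const$t0) / p[["thetaP"]]
  y <- pmax(x - const$xS, 0) / const$wS
  p[["hS"]] * y^2 / (1 + y^2)
}

# Brute-force total-curve landmark oracle on a dense age grid: pubertal peak
# as the velocity argmax restricted to a mid-pubertal age band, onset as the
# argmin before it, end as the first 1 cm/yr downcrossing after it.
oracle_t_landmarks <- function(p, const, step = 1e-4,
                               window = c(3, 21), peak_band = c(10, 17)) {
  grid <- seq(window[1], window[2], by = step)
  hv <- qeps_evaluate(p, const, grid, order = 1)$T
  band <- which(grid >= peak_band[1] & grid <= peak_band[2])
  i_phv <- band[which.max(hv[band])]
  i_on <- which.max(-hv[seq_len(i_phv)])
  after <- which(hv < 1 & seq_along(grid) > i_phv)
  list(onset = grid[i_on], phv = grid[i_phv], end = grid[after[1]])
}

# Noise-free record sampled densely from known parameters.
noise_free_record <- function(p, const, sex = const$sex,
                              ages = c(0, 0.3, 0.6, seq(1, 19, by = 0.5))) {
  h <- qeps_evaluate(p, const, ages, order = 0)$T
  growth_record("truth", sex, age_years = ages, height_cm = h)
}

# QC fixture builder for the MathSelect tests.
make_qc <- function(rmse = 0.3, stud = 2, ciA = 0.5, ciP = 1.5, relT = 0.005,
                    nmeas = 21, nep = 8, gap = 2, dphv = 0.2,
                    flags = character(0)) {
  structure(list(rmse_cm = rmse, max_abs_studentized_residual = stud,
                 ci_width_AgeP50_y = ciA, ci_width_Pmax_cm = ciP,
                 rel_ci_width_Tmax = relT, n_measurements = nmeas,
                 n_epochs_covered = nep, max_gap_years = gap,
                 abs_diff_AgeP50_vs_empirical_phv_y = dphv, flags = flags),
            class = "qeps_qc")
}

random_qc <- function() {
  make_qc(rmse = rlnorm(1, -1.2, 0.3), stud = rlnorm(1, 0.7, 0.3),
          ciA = rlnorm(1, -0.7, 0.4), ciP = rlnorm(1, 0.4, 0.4),
          relT = rlnorm(1, -5.5, 0.4), nmeas = sample(15:30, 1),
          nep = sample(6:8, 1), gap = runif(1, 1.2, 3),
          dphv = abs(rnorm(1, 0, 0.3)))
}

# Simulate-and-fit a cohort once and cache it: the CI-coverage and
# parameter-recovery checks share the same 200-subject experiment.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_experiment <- function(n = 200, seed = 42, n_draws = 200) {
  key <- sprintf("exp_%d_%d_%d", n, seed, n_draws)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  coh <- sample_cohort(n, seed = seed, compute_truth_summary = FALSE)
  rows <- lapply(seq_along(coh), function(i) {
    s <- coh[[i]]
    f <- tryCatch(fit_individual(s$record), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    ci <- landmark_cis(f, n_draws = n_draws, seed = seed + i)
    r <- ci[ci$variable == "AgeP50", ]
    true_agep50 <- qeps_constants(s$record$sex)$t0 + s$true_params[["thetaP"]]
    data.frame(
      sex = s$record$sex,
      true_agep50 = true_agep50,
      est_agep50 = r$estimate,
      covered = r$lower95 <= true_agep50 & true_agep50 <= r$upper95,
      true_pmax = s$true_params[["hP"]],
      est_pmax = f$params[["hP"]])
  })
  out <- do.call(rbind, rows)
  .acceptance_cache[[key]] <- out
  out
}

# Minimal fit-like object (true parameters, no optimizer) for reference
# building, where only params/constants/sex are consulted.
fitlike <- function(p, const, id = "X") {
  structure(list(params = p, constants = const, sex = const$sex,
                 subject_id = id, converged = TRUE), class = "qeps_fit")
}
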
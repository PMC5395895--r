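# qepsgrowth

Individualized analysis of human pubertal growth with the QEPS model.

Children differ enormously in *when* they enter puberty and in *how much*
they grow during it, and most growth references cannot separate the two.
The QEPS model decomposes an individual's total height curve into four
shape-invariant growth functions,

    T(age) = Q(age) + E(age) + P(age) − S(age)

— a Quadratic function for the continuous growth from fetal life to
adulthood, a negative Exponential function for the rapid declining
fetal/infancy growth, a Pubertal function for the specific pubertal spurt,
and a Stop function for the decline of growth toward adult height. The
shapes are fixed per sex; each child is described by exactly six modifying
parameters (four height scales hQ, hE, hP, hS in cm; two time scales
thetaE, thetaP in years). Because puberty gets its own additive component,
the model yields landmark variables that are not otherwise computable from
longitudinal height data:

* onset of puberty: minimum total height velocity (`AgeT_onset`) or the
  age at 1%/5% of the pubertal gain (`AgeP1`, `AgeP5`);
* mid-puberty: peak height velocity (`AgeT_phv`, `AgeP_phv`) or 50% of
  the pubertal gain (`AgeP50`);
* end of puberty: velocity fallen to 1 cm/year (`AgeT_end`) or 95%/99% of
  the pubertal gain (`AgeP95`, `AgeP99`);
* gains: total pubertal gain decomposed exactly as
  `Tgain = Pgain + QESgain`, plus the asymptotic pubertal gain `Pmax`;
* per-individual 95% confidence intervals for all of the above
  (parametric bootstrap), a composite data-quality score (*MathSelect*,
  calibrated as a reference-cohort exceedance probability), and
  tempo-adjusted SD-scores that compare a child with the population at
  the same *pubertal* (not chronological) age.

The package is aimed at growth researchers and auxologists working with
longitudinal height records (one row per measurement: subject, sex,
decimal age, height in cm). The original study cohort is not publicly
deposited, so the package ships a synthetic-cohort generator calibrated
to the published population moments; every analysis step is exercisable
without any external data. See `vignette source in vignettes/qeps-methods.Rmd`
for the model, calibration and design notes.

## Worked example

Simulate a girl with a realistic school-health measurement schedule, fit
her curve, and extract the pubertal variables:

```r
library(qepsgrowth)

coh <- sample_cohort(2, sex_ratio = 1, seed = 42)   # synthetic cohort, truth stored
fit <- fit_individual(coh[[1]]$record)
fit
#> QEPS fit for S0001 (F): 21 points, residual SD 0.271 cm
#>      hQ      hE  thetaE      hP  thetaP      hS
#> 108.096  63.933   0.550  13.086  14.619   5.806

pubertal_summary(fit$params, fit$constants)
#> QEPS pubertal summary:
#>  AgeT_onset    AgeT_phv    AgeT_end       AgeP1       AgeP5      AgeP50
#>      10.867      13.482      16.480      10.504      11.576      13.969
#>      AgeP95      AgeP99    AgeP_phv       AgeS0        Pmax        Emax
#>      17.087      18.933      13.758      15.022      13.035      63.933
#>        Qmax        Smax        Tmax    Tpubgain    Ppubgain  QESpubgain
#>     108.096       4.863     180.201      25.193      12.431      12.774
#>      dP5_95      dP1_99 dTonset_end
#>       5.511       8.429       5.613
```

This child enters puberty late (minimum height velocity at 10.9 y,
mid-spurt `AgeP50` at 14.0 y vs the girls' population mean of 12.09 y),
gains 13.0 cm from the pubertal function (`Pmax`), and reaches a modelled
adult height of 180.2 cm (`Tmax = Emax + Qmax + Pmax − Smax`, an exact
identity). Per-individual confidence intervals:

```r
landmark_cis(fit, seed = 1)
#>      variable estimate lower95 upper95 n_defined unavailable
#>        AgeP50    13.97   13.86   14.08       200       FALSE
#>          Pmax    13.03   12.54   13.65       200       FALSE
#>          Tmax   180.20  179.83  180.61       200       FALSE
#>   ...
```

The generator stored this subject's true mid-spurt age, 14.01 y — inside
the [13.86, 14.08] interval. Cohort-level tools follow the same pattern:
`fit_cohort()`, `cohort_landmarks()` (one CSV-ready row per child),
`cohort_qc()` / `mathselect()` for quality filtering, and
`build_reference()` / `sds_estimates()` / `tempo_aligned_curves()` for
tempo-adjusted SD-scores. A command-line pipeline over the same functions
is available as `exec/qeps` (subcommands `simulate`, `fit`, `landmarks`,
`qc`, `reference`, `sds`).

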
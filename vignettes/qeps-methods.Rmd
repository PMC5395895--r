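---
title: "The QEPS growth model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The QEPS growth model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qepsgrowth)
```

## The model

The QEPS model describes an individual's height from late fetal life to
adulthood as the sum of four shape-invariant growth functions,

$$T(a) = Q(a) + E(a) + P(a) - S(a),$$

where $a$ is decimal age in years since birth. The shapes are shared by a
whole cohort (per sex); individuals differ only through six modifying
parameters: four height scales ($h_Q, h_E, h_P, h_S$, cm) and two time
scales ($\theta_E, \theta_P$, years). The components are, with
$u = a - t_0$ (where $t_0 < 0$ is the prenatal growth origin, about six
weeks after conception for a term birth) and scaled age $x = u/\theta_P$:

* **E — infancy**: $E(u) = h_E\,(1 - e^{-u/\theta_E})$, the rapid,
  saturating fetal/infancy growth;
* **Q — childhood**: $Q(u) = h_Q\,(2v - v^2)$, $v = \min(u/U, 1)$, a
  quadratic whose velocity declines linearly through childhood and reaches
  zero at age $t_0 + U$ (the cap keeps $Q$ bounded; the stop function
  handles the approach to the adult plateau well before that);
* **P — puberty**: $P(x) = h_P\,\Lambda(z)^2$,
  $z = (x - 1)/s_P + z_{50}$, with $\Lambda$ the standard logistic and
  $z_{50} = \ln(1+\sqrt 2)$ so that $P = h_P/2$ exactly at $x = 1$. The
  squared logistic is the "quadratic, logistic" pubertal shape; its peak
  velocity falls where $\Lambda = 2/3$, i.e. at $4/9 \approx 44\%$ of the
  pubertal gain, consistent with the reference cohort's reported median
  P-fraction at mid-puberty (43% girls, 45% boys);
* **S — stop**: $S(x) = h_S\,y^2/(1+y^2)$ with $y = (x - x_S)/w_S$ for
  $x > x_S$ and $S = 0$ before. $S$ is $C^1$ at its onset
  $\mathrm{AgeS0} = t_0 + \theta_P x_S$ with a jump in curvature there —
  the characteristic break in the height-acceleration curve.

The exact functional forms used by the model's originators are published
separately and not reproduced here; the forms above are canonical choices
that satisfy every qualitative and quantitative property the applied work
states (component shapes, percentile identities, velocity-peak fractions,
acceleration break). They are documented as this package's own
reimplementation, not a clone. One structural consequence: tying both the
pubertal and stop time scales to the single $\theta_P$ (forced by the
six-parameter count) couples spurt timing and duration proportionally. The
reference cohort's small printed SD of the P5–P95 duration (~0.21 y)
against the much larger SD of AgeP50 (~0.95 y) hints that the original
model may decouple them; with six parameters and one pubertal time scale
this is the simplest faithful choice, and it is documented rather than
hidden. Whether $x_S$ is a population constant or individual in the
original is likewise unstated; it is a per-sex constant here.

## Shape constants and their calibration

`qeps_constants(sex)` returns the per-sex shapes. Defaults:

| constant | girls | boys | meaning | calibration |
|---|---|---|---|---|
| `t0` | −0.65 y | −0.65 y | prenatal origin | term birth at 40 wk |
| `U` | 20.65 y | 20.65 y | Q horizon | Q velocity reaches 0 at age 20 |
| `sP` | 0.0770 | 0.0611 | P width | mean P5–P95 duration 4.80 / 4.32 y at the cohort-mean $\theta_P$ |
| `xS` | 1.072 | 1.118 | S onset (scaled age) | P-fraction completed at AgeS0: 74% / 89% |
| `wS` | 0.15 | 0.15 | S width | plateau within ~2 y of AgeS0 |
| `adult_eval_age` | 20 y | 20 y | where component maxima are read | — |

The duration calibration is exact in closed form:
$\mathrm{AgeP95}-\mathrm{AgeP5} = \theta_P\, s_P\,
(\mathrm{logit}\sqrt{0.95} - \mathrm{logit}\sqrt{0.05})$, giving 4.80 y at
$\theta_P = 12.74$ (girls) and 4.32 y at $\theta_P = 14.45$ (boys).

## Landmarks

All P-function landmarks are closed-form inversions
(`age_at_p_fraction()`): the age at fraction $q$ of the pubertal gain is
$t_0 + \theta_P (1 + s_P(\mathrm{logit}\sqrt q - z_{50}))$. Total-curve
landmarks (`t_landmarks()`) bracket velocity extrema on a 0.01-year grid
and refine the acceleration roots with a tolerance-1e-10 bracketing root
finder — well below measurement resolution and cheap at desk scale. The
search window default `[3, 25]` years excludes the infancy velocity spike;
the lower bound is a package choice since children's velocity also has an
infancy minimum.

Two detection rules deserve note. The childhood velocity at age 3 can
exceed the pubertal peak, so PHV is *not* the global velocity maximum: it
is the largest interior local maximum whose velocity still exceeds the
1 cm/yr end-of-growth threshold, and onset is the deepest local minimum
before it, also required to lie above 1 cm/yr. Without the threshold
condition, the stop function's velocity tail (a shallow dip-and-rebound
after AgeS0) masquerades as a "spurt" whenever $h_P$ is small. Subjects
whose velocity has no qualifying minimum/maximum pair are flagged
`onset_undetectable` / `phv_undetectable`, matching the observation that
children with very low pubertal gains lack these landmarks; no threshold
on $h_P$ itself is used. "100% of the pubertal function", needed as a gain
interval endpoint, is undefined for an asymptotic function and is
implemented as the age where $P$ reaches 99.9% of $h_P$ (error < 0.1% of
$h_P$ on any gain). `Ppubgain` is defined as $0.95\,h_P$ (the gain past
AgeP5) exactly.

## Fitting

`fit_individual()` minimizes, over $\beta = (h_Q, h_E, \theta_E, h_P,
\theta_P, h_S)$ in log space,

$$\sum_i w_i\,(h_i - T(a_i;\beta))^2 +
\lambda \sum_j \left(\frac{\log\beta_j - \mu_j}{\sigma_j}\right)^2,$$

by Levenberg–Marquardt from three deterministic starts (prior mean,
$\pm 0.5$ prior SD on $\log\theta_P$). The log parameterization enforces
positivity without constrained optimization. The ridge centres
$(\mu_j, \sigma_j)$ are per-sex moment-matched log-scale priors from the
published cohort tables; $\lambda = 0.01\,n$ by default, so the penalty
stabilizes weakly identified parameters (notably $\theta_E$ and $h_S$ on
sparse records) while vanishing asymptotically. On a noise-free dense
record the default penalty displaces parameters by under 1%; unpenalized,
recovery is exact to optimizer tolerance.

**Weights.** Default weights are not uniform: measurements before age 2
(supine length, error SD ≈ 0.45 cm) are down-weighted by the error-variance
ratio against standing height (≈ 0.27 cm). With uniform weights the pooled
residual SD mixes the two error scales (≈ 0.38 cm) and every pubertal-age
CI inherits ~40% spurious width. Pass `weights = rep(1, n)` for the
uniform alternative.

**Covariance and CIs.** The parameter covariance is
$\hat\sigma^2 (J^\top J)^{-1}$ from the Jacobian of the penalized residual
vector at the optimum, $\hat\sigma^2$ from the data residuals on $n - 6$
degrees of freedom. `landmark_cis()` is a parametric bootstrap: parameter
draws from the multivariate **t** with $n - 6$ df (location $\hat\beta$,
scale the asymptotic covariance), every landmark recomputed per draw,
percentile 2.5/97.5 intervals. The t rather than the normal matters at
these sample sizes: with ~21 measurements the standardized errors of
$\theta_P$ in simulation have SD ≈ 1.08 (the $\sqrt{df/(df-2)}$ inflation
from estimating $\sigma$), and normal draws cover the truth only ~90% of
the time at nominal 95%; t draws restore ~93–95%. Landmarks are non-smooth
near the no-spurt boundary, which is why a bootstrap was chosen over the
delta method; draws that land in the no-spurt region are counted, and a
variable undefined in more than half the draws gets no CI. Near-singular
covariances are repaired with a 1e-8 diagonal ridge and flagged.

## Data quality

`mathselect()` scores a curve against a reference cohort of acceptable
fits with exceedance semantics: the score is the expected fraction of the
reference with *higher* quality, so 0 is better than the whole reference
and 1 worse than all of it. Nine per-subject variables feed it — fit error
(RMSE, largest studentized residual), landmark precision (CI widths of
AgeP50 and Pmax, relative CI width of modelled adult height), and data
coverage (measurement count, epochs covered of the eight selection epochs,
largest age gap, disagreement between AgeP50 and the empirical PHV age).
The published nine-variable list is in an unavailable supplement; this set
covers the three facets the applied results discuss and is documented as a
reimplementation. Each variable is oriented so larger = worse, ranked
against the reference distribution, the nine ranks averaged, and the
average ranked again cohort-level — which makes self-scores uniform on
[0, 1] by construction (tested by Kolmogorov–Smirnov) and thresholding
monotone. Default keep-thresholds are 0.975 (permissive) and 0.68
(strict).

Outlier screening studentizes residuals with a robust scale
(1.4826 × MAD): an RSS-based scale absorbs the outlier being screened —
with ~21 points and 6 parameters a single gross error is mathematically
capped near $\sqrt{n-6} \approx 3.9$, so the conventional cutoff of 4
could never fire. The curve-level flags are: mid-puberty disagreement
(|AgeP50 − empirical PHV| strictly greater than 0.66 y, float-guarded),
any robust studentized residual above 4, fitted velocity above 1 cm/yr at
the last measurement (adult height not reached), and Pmax below half the
width of its 95% CI (indistinguishable from no spurt). The "50% of the
CI" rule is interpreted as half the CI *width* in cm; the source sentence
is ambiguous between width and half-width and does not say so explicitly.

## Tempo-adjusted SD-scores

`build_reference()` stores per-sex means/SDs of every landmark variable
and pointwise mean/SD bands of the fitted T, P and QES heights on a
relative-age grid (−6 to +10 y, step 0.1) aligned to each subject's AgeP5
— AgeP5, not AgeP50, is the alignment anchor. SD-scores are plain
$(x-\mu)/\sigma$; no LMS/skewness machinery, following the source's
mean/SD standardization. Curve SDS are computed pointwise on heights and
assume pointwise-Gaussian bands; that assumption is documented rather than
verified. Aligning on AgeP5 removes timing variance: in a cohort varying
only $\theta_P$, the aligned P band is pointwise narrower than the
chronological-age band (a tested invariant). Subjects without a detectable
spurt have no AgeP5 and are excluded from curve bands (counted in the
reference metadata). Whether the original SDS referenced the
quality-filtered or the full cohort is unknown; here the caller chooses
the cohort that goes into `build_reference()`.

## The synthetic cohort

No individual-level study data are deposited, so `sample_cohort()`
generates cohorts whose *population moments* match the published tables;
it is a calibration, not ground truth, and synthetic throughout:

* marginals: height scales and $\theta_E$ log-normal, $\theta_P$ normal
  truncated at 3 SD (a log-normal would skew AgeP50, which the source's
  normality checks do not support);
* moments: $h_Q$ 97.61/7.57 (F), 104.05/8.02 (M); $h_E$ 62.86/2.87,
  65.08/2.88; $h_P$ 12.78/3.65, 17.34/3.63; $\theta_P$ 12.74/0.95,
  14.45/0.96 (so mean AgeP50 is 12.09/13.80); mean $h_S$ 5.99/6.04 from
  the adult-height identity, SD 0.60 chosen;
* $\theta_E$: mean 0.54 y (F) / 0.58 y (M), SD 0.05 y, calibrated so the
  simulated mean *birth length* matches the printed 49.9 / 50.5 cm without
  inflating its SD (≈ 2.1 cm). A slower infancy time scale would put mean
  birth length near 44 cm and its lognormal tail below the 30 cm record
  floor;
* dependence: Gaussian copula, the only nonzero correlation being
  cor($h_P$, $h_Q$) = −0.60 (F) / −0.53 (M), reflecting the published
  negative regression of pubertal gain on Qmax; $h_P$ ⟂ $\theta_P$, so
  pubertal gain is independent of timing;
* schedule: the eight selection epochs (birth; ≥2 infancy visits; then
  roughly annual school-health visits), uniform ±0.1 y jitter; `dense`
  adds quarterly pubertal visits, `sparse` drops one droppable epoch;
* noise: Gaussian, SD 0.45 cm below age 2 (supine length) and 0.27 cm
  above — literature-typical conventions; the study's true error
  magnitudes are unreported.

What passing tests on this cohort do **not** show: behaviour under real
data's non-Gaussian errors, transcription outliers beyond those injected,
informative dropout, secular trends, or family correlation — none of which
are simulated. Population-mean landmark ages from the canonical bases also
differ from the cohort's printed means where the original basis shapes
differ from ours (e.g. the modelled girls' mean AgeT_END comes out later
than the printed 15.0 y); printed population tables are calibration
targets only where the design says so, never reproduction claims.

## Problem sizes and numerical choices

The shipped experiments use desk-scale sizes chosen to make sampling error
small relative to the tolerances they are tested at: 200 subjects × 200
bootstrap draws for CI coverage, 1000 subjects for generator moment
checks, 500 members for MathSelect calibration, 100 random draws for
landmark-oracle agreement. Root bracketing uses a 0.01-y grid with 1e-10
refinement; derivative checks use central differences at 1e-4 y; the
percentile-inversion identities are closed-form and tested at 1e-8–1e-9.
Degenerate inputs (absent spurt, non-plateauing parameters, zero-variance
reference cohorts, records with fewer than six points) raise flags or
typed validation errors rather than silent results.
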
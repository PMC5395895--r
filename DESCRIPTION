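Package: qepsgrowth
Title: QEPS Growth Model for Individual Pubertal Growth Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the four-component QEPS human growth model (Quadratic,
    Exponential, Pubertal, Stop) to individual longitudinal height data and
    derives the pubertal growth variables it defines: onset, mid-puberty and
    end-of-puberty landmark ages from both the total curve and the pubertal
    component, component maxima and pubertal gains, with per-individual
    parametric-bootstrap confidence intervals. Includes a composite
    curve-quality score (MathSelect) calibrated as a reference-cohort
    exceedance probability, tempo-adjusted SD-score references aligned on
    pubertal onset, and a synthetic-cohort generator emulating a
    school-health measurement schedule so that every analysis step can be
    exercised without access to the original study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    MASS,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
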
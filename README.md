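# kbplan

Knowledge-based DVH prediction and plan-quality auditing for arc-therapy
treatment planning.

## What it does, and for whom

Medical physicists configuring a volumetric-modulated-arc-therapy (VMAT)
optimizer must supply per-structure dose-volume constraints, and what is
achievable for an organ at risk (OAR) depends on each patient's
geometry. `kbplan` implements a knowledge-based planning engine that
learns from a library of prior approved plans and, for a new patient,
predicts the achievable cumulative dose-volume histogram (DVH) of every
structure with an uncertainty band, generates optimization objectives
just below the band's lower edge, and audits resulting plans against a
set of clinical dose-volume endpoints. A synthetic virtual-patient
generator with a known, recoverable geometry-to-DVH structure makes the
whole pipeline testable without clinical data.

## The model

Any cumulative DVH is represented as the population mean plus a weighted
sum of principal components (PCs) plus a residual,

    v(x) = m(x) + Σᵢ sᵢ Pᵢ(x) + r(x),

on a common relative-dose grid (0–110% of prescription, fractional
volume). The geometric predictor is the geometry-based expected dose
(GED): a DVH-shaped curve assigning each sub-volume of a structure the
dose the target is expected to contribute, via exponential fall-off
kernels in the signed distance to the target surface (separate in-field
and out-of-field kernels). Each DVH PC score is regressed by ordinary
least squares on the GED PC scores plus scalar features (log target
volume, log structure volume, in-field fraction, number of arcs):

    sᵢ = β₀ᵢ + Σⱼ βᵢⱼ tⱼ + γᵢᵀ f + εᵢ.

A predicted DVH is the regression reconstruction; its in-field band
half-width adds the PCs in quadrature weighted by the per-component
regression standard error, h(x) = √(Σᵢ (SEᵢ·Pᵢ(x))²), and the low-dose
out-of-field segment uses the training population's pointwise mean ± 1
SD. Training diagnostics include 10-fold cross-validated goodness of
estimation, a reduced average chi-square, a pooled R², Cook's distance
(threshold 4) and externally studentized residuals (threshold 3) for
outlier candidates, and a recommended case count of five times the
number of regression parameters. Structures with fewer than 20 cases
are not modelled.

See the methods vignette (`vignettes/kbplan-methods.Rmd`) for the full
account of assumptions, defaults and design choices.

## Worked example

Audit the packaged violation-table worked example (45 re-optimized
training patients, 8 endpoints each), then train a model on a synthetic
45-patient cohort and predict a new case:

```r
library(kbplan)

clinical <- evaluateTable5("closed_loop", "clinical")
test     <- evaluateTable5("closed_loop", "closed_loop")
clinical
#> <PassFailReport> 45 patients x 8 endpoints: 11 violations (3.1%), 7 patients affected, max 4 simultaneous
test
#> <PassFailReport> 45 patients x 8 endpoints: 4 violations (1.1%), 3 patients affected, max 2 simultaneous
violationSummary(clinical, test)
#> $sharedFailures    [1] 4
#> $newFailures       [1] 0
#> $resolvedFailures  [1] 7
#> $netImprovementPct [1] 2
```

Every model-based failure was already a failure of the original plan,
and the pass-rate improves by 2.0 percentage points — the closed-loop
pattern the engine is expected to reproduce.

```r
co <- generateCohort(cohortConfig(nPatients = 45, seed = 7))
kb <- fitKBModel(co, kbConfig())

new  <- generateCohort(cohortConfig(nPatients = 1, seed = 8))[[1]]
pred <- predictStructure(kb, "right_kidney",
                         new$structures$right_kidney$geometry,
                         new$field, new$targetVolume)
pred
#> <PredictedDVH> right_kidney: 100 dose bins, band width 0.00-12.19%

generateObjectives(pred, defaultObjectiveRules(names(kb@structures)),
                   new$field$prescription)
#>     structure        kind doseGy volumePct priority
#>  right_kidney upper_point  21.88        10       80
#>  right_kidney upper_point  10.11        50       80
#>  right_kidney upper_point   1.76        90       80
```

For this patient the model predicts a right-kidney V15Gy of 36.2%
(band 32.3–40.1%), and the generated objectives ask the optimizer for
doses strictly below the band's lower edge at the 10/50/90% volume
levels (2% of prescription margin).

A command-line wrapper covering
`simulate | train | report | predict | evaluate` ships in
`inst/cli/kbp.R`:

```sh
Rscript inst/cli/kbp.R simulate --n 45 --seed 7 --out cohort/
Rscript inst/cli/kbp.R train --cohort cohort/ --out model/
```

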
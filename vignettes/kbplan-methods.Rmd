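---
title: "Knowledge-based DVH prediction: models, assumptions and design choices"
author: "kbplan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-based DVH prediction: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kbplan)
```

## The problem

Inverse treatment planning for volumetric modulated arc therapy needs
per-structure dose-volume constraints before the optimizer can run, and
what is *achievable* for an organ at risk depends strongly on patient
geometry: how close the organ sits to the target, how much of it lies
inside the beam apertures, how large the target is. Knowledge-based
planning turns a library of previously approved plans into a predictive
model that, for a new patient, estimates the achievable cumulative
dose-volume histogram (DVH) of each structure together with an
uncertainty range, and places optimization objectives just below the
lower edge of that range.

`kbplan` implements that engine end to end: curve representation and
metrics, the geometric feature construction, model training with
quality diagnostics, band prediction with automatic objective
generation, clinical endpoint auditing, and a synthetic virtual-patient
generator used to validate every statistical component against a known
ground truth.

## The model

### Curve spaces

All modelling happens on a common coordinate system: curves are
resampled to a 100-point uniform grid of *relative* dose (0 to 110% of
the prescription) with volume expressed as a fraction in [0, 1]. A
shared grid is required by the principal-component decomposition; the
110% span covers clinically occurring hot spots, and 100 points
resolve every reported metric well below its clinical precision (the
grid step is about 0.7 Gy at a 60 Gy prescription, and metric
evaluation on absolute curves uses a 0.05 Gy default bin).

### DVH decomposition

Any cumulative DVH of a structure population is modelled as the
population mean plus a weighted sum of principal components plus a
residual:

  v(x) = m(x) + sum_i s_i P_i(x) + r(x)

The components `P_i` are the eigenvectors of the centred curve
covariance, ordered by explained variance; the smallest set explaining
at least 95% of the variance is retained, capped at 5 components. The
cap keeps the number of regression parameters far below the number of
training cases; the 95% target makes the reconstruction error
negligible against inter-plan variability.

### Geometry-based expected dose

The geometric feature is itself a curve: the geometry-based expected
dose (GED) assigns each sub-volume of a structure the dose the target
is expected to contribute to it, and accumulates those doses into a
DVH-shaped curve. The dose assignment is an exponential fall-off in
distance to the target surface:

* inside the target (signed distance <= 0): the prescription dose;
* in-field sub-volumes: `Rx * exp(-kIn * d)` with `kIn = 0.05` per mm;
* out-of-field sub-volumes: `Rx * fOut * exp(-kOut * d)` with
  `fOut = 0.3`, `kOut = 0.15` per mm.

The vendor's exact construction is proprietary; these kernels are this
package's own operationalization. They reproduce the property the
model actually consumes — a monotone, field-aware mapping from
distance to expected dose that separates a high-dose in-field region
from a scatter-dominated out-of-field region — while remaining
analytically checkable. The parameters live in `kernelParams()`
(configuration, not code), so a site can calibrate them; whether a
vendor engine integrates over individual arc control points or uses a
field-aggregate approximation is not decidable from published
descriptions, and the kernel abstraction covers both readings.

### Score regression

Each structure's model regresses every retained DVH component score by
ordinary least squares on the GED component scores plus four scalar
features: log target volume, log structure volume, the in-field volume
fraction, and the number of arcs. Volumes enter on the log scale
because they span two orders of magnitude in the population.
Predictors are *not* standardized: raw-scale coefficients keep the
interpretation "DVH score units per GED score unit", which is also the
scale on which the synthetic ground truth is defined and recovered.
Coefficient standard errors come from the usual OLS theory; the
per-component residual standard error feeds the prediction band.

A rank-deficient predictor matrix is an error naming the collinear
columns at the single-structure level; the cohort-level trainer
instead drops redundant columns with a message, because degenerate
structures arise legitimately (for the target, structure volume
coincides with target volume and the in-field fraction is constant 1).

### In-field and out-of-field segments

The regression models the high-dose behaviour; the low-dose tail of an
OAR is dominated by scatter and is modelled by the pointwise mean and
standard deviation of the training curves. The partition is at 20% of
the prescription on the relative-dose axis — a free modelling choice
(the published description requires the dichotomy but not the cut);
0.2 cleanly separates the fall-off region the regression can explain
from the scatter floor in all the organ families shipped with the
generator. At prediction time the two segments are blended with a
linear cross-fade over 5 grid points to avoid a seam.

### Prediction bands and objectives

The most probable curve is the regression reconstruction. Its in-field
half-width adds the components in quadrature, each weighted by its
regression residual standard error:

  h(x) = sqrt( sum_i (SE_i * P_i(x))^2 )

and the out-of-field band is the stored mean plus or minus one
standard deviation. Raw component combinations need not be monotone,
so all three band curves are projected onto the non-increasing cone by
isotonic regression (pool-adjacent-violators on the negated curve) and
clamped to [0, 100]%. Isotonic projection is order-preserving, which
is why the band ordering lower <= most-probable <= upper survives the
projection; this is exercised by a 1000-draw property test.

Optimization objectives are placed *strictly below* the lower band:
point objectives at each rule's volume level take the lower-band dose
minus a margin of 2% of the prescription (the published workflow
states "below the lower limit" without an offset; 2% is this package's
declared default and a parameter). Line objectives sample the same
lower-minus-margin curve on a fixed volume grid. Target coverage rules
take the lower-band dose at the coverage level without the margin.
Priorities are template data (`defaultObjectiveRules()`), with target
coverage highest — the vendor's trade-off balance is undisclosed, so
priorities are deliberately not computed.

## Training diagnostics

* **Goodness of estimation** is the 10-fold cross-validated mean
  squared error between held-out curves (volume-fraction units) and
  their estimation-model reconstruction. Fold membership is drawn
  deterministically from a seed and keyed to case labels, so the
  result does not depend on storage order. The *estimation model*
  (pure PC + regression reconstruction) is scored, not the blended
  clinical band: the out-of-field segment of the band is a population
  mean/SD model whose deviation from an individual curve is population
  variance, not estimation error.
* **Average chi square** is, per component, the classical residual
  variance estimate (RSS over residual degrees of freedom) divided by
  a robust, median-absolute-deviation-based estimate of the same
  variance, averaged over components. For a well-specified model with
  clean Gaussian residuals the ratio concentrates at 1; gross outliers
  or heavy tails inflate the numerator faster than the robust
  denominator, pushing it above 1. The vendor metric is documented
  only as "closer to one is better"; this reduced-chi-square reading
  is the package's interpretation and is calibrated by simulation
  (n = 500 cohorts land in [0.8, 1.2]).
* **Model fit** is the pooled coefficient of determination of the
  score regressions (1 minus pooled RSS over pooled TSS), at most 1.
* **Recommended cases**: five times the number of regression
  parameters, reported only when the available cases fall short;
  structures with fewer than 20 cases are excluded from modelling
  entirely, with a warning.

### Outlier candidates

Influence diagnostics run per component regression: Cook's distance
`D_i = r_i^2/(p s^2) * h_ii/(1-h_ii)^2` with reporting threshold 4,
and externally studentized residuals `t_i = r_i/(s_(i) sqrt(1-h_ii))`
with default threshold |t| >= 3 (no published value exists; 3 is the
conventional choice). A case is reported with the maximum over
components and the reasons that fired. Exact leverage points
(`h_ii = 1`) are reported with infinite influence rather than failing.
Candidates are *reported, never removed* — the modelling practice this
package follows keeps influential cases in the training set unless a
human review finds a genuine contouring or planning anomaly. Both
diagnostics are verified against explicit leave-one-out refits for
every dataset size up to 30.

## Clinical endpoint auditing

The default endpoint set is the acceptance protocol: spinal cord
D_1cm3 < 45 Gy, both kidneys V_15Gy < 35%, stomach V_36Gy < 5%,
esophagus D_1cm3 < 60 Gy and V_55Gy < 30%, normal liver V_30Gy < 30%,
target D_98% > 90% of prescription. A second named set (`"tables"`)
carries the stomach V_35Gy and esophagus V_30Gy variants that appear
in the summary tables; the two sets are both provided and neither is
silently preferred. Comparators are strict in the passing direction: a
value exactly at its limit passes (the transcribed violation table
never bolds a boundary value, so the convention is unconstrained; this
one is declared and configurable at the endpoint level).

The packaged violation-table fixture reproduces the published
closed-loop and open-loop counts exactly. One documented discrepancy:
the open-loop analysis prints a denominator of 224 dose-volume points
although 25 patients times 8 endpoints gives 200. `evaluateTable5()`
uses the printed 224 when reproducing the printed percentages and
emits a message flagging the discrepancy; all counts are
denominator-free.

Metric conventions: D_x% is the smallest dose received by the hottest
x% of the volume with linear interpolation and ties resolved toward
the lower dose; mean dose integrates the differential DVH with a
midpoint rule per bin (bin-width robust); the homogeneity index is
(D5 - D95)/mean; the conformity index is the body volume receiving at
least 95% of the prescription divided by the target volume — the body
V95 volume is an explicit input because it is not computable from the
target curve alone.

## The synthetic cohort generator

Real training libraries are clinical data and are not distributable,
so validation runs on virtual patients whose population statistics
match the study population and whose geometry-to-DVH mapping is known
exactly.

**Population.** Target volumes are log-normal with arithmetic mean 596
and SD 538 cm^3, rejection-truncated to [54, 2188] cm^3.
Prescriptions sit at three representative levels 60/42/36 Gy (inside
the reported bands "60 Gy or more", "40-45 Gy", "less than 40 Gy")
with mix 55/40/5 — the reported proportions sum to 110%, an evident
misprint, and any non-normalized mix is renormalized with a message.
Plans use 2-4 partial arcs with a non-coplanar arc in 40/45 of cases.

**Geometry.** Each organ's signed-distance histogram comes from a
shifted gamma family with per-organ shape/scale and per-patient
log-normal multipliers on shift and scale; the in-field fraction is a
logit-normal draw around an organ-specific mean. No organ-level
geometric statistics are published, so these families are declared
assumptions chosen to give clinically plausible GED curves (kidneys
and esophagus mostly out-of-field, normal liver wrapping the target),
not estimates.

**Embedded truth.** The generator computes every patient's GED curve,
runs the same PCA the trainer will run, and sets the DVH component
score as an exact linear function of the two leading GED scores and
the four scalar features, with fixed coefficients scaled by frozen
per-organ calibration constants (the population SDs of the GED scores,
measured once on a 400-patient reference sample of the family). Using
the trainer's own coordinates makes the regression exactly correctly
specified, so a noise-free cohort is recovered to machine precision
and coefficient confidence intervals attain nominal coverage on noisy
cohorts.

One deliberate simplification: the embedded DVH structure uses a
*single* component per organ, shaped as a tapered falloff-shift bump
whose slope is dominated by the mean curve's slope. With two or more
additive components at realistic amplitudes the linear construction
provably leaves the monotone cone in the flat curve regions, and the
repair projection would break the exact-reconstruction property the
recovery tests rely on. The fitted model still retains several
components on noisy cohorts (the extra ones capture noise modes), so
the multi-component code paths are exercised throughout. Because the
geometry scores are unbounded, extreme draws (roughly one curve in two
thousand) can still exceed the monotone-safe amplitude; such curves
are projected and then deviate from their recorded linear
reconstruction by below 1e-3 in volume fraction. Exactness tests pin
their seeds.

**Noise.** Curve-level noise is a smooth Gaussian field (kernel
correlation length 0.15 in relative dose) with unit pointwise
variance, modulated by an envelope proportional to m(1-m) — zero where
the curve is pinned at 100% or 0%, largest mid-falloff — and
normalized so that `noiseSd^2` (default 0.02^2) equals the
grid-averaged injected variance. That normalization is what makes
"cross-validated goodness approximately equals noiseSd squared" a
well-defined calibration target. Smoothness matters: white noise would
be largely removed by the monotone projection, silently deflating the
noise floor.

**What passing does and does not show.** The generator emulates
population statistics, geometric dose gradients and curve-level noise;
it does not emulate contouring variability, correlated multi-organ
trade-offs made by human planners, delivery constraints, or optimizer
behaviour. Passing recovery and calibration tests therefore validates
the statistical machinery, not clinical performance on real plans.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at the study's scale
where that is feasible on a desk machine: 45-patient training and
25-patient validation cohorts for the pipeline, 50 replicates of
200-patient cohorts for coefficient coverage, single 500-patient
cohorts for chi-square calibration and band coverage, and exhaustive
leave-one-out oracles up to n = 30. Degenerate inputs are handled
explicitly: zero-variance curve populations yield zero components and
a mean-only model; lm fits with zero residuals report a model fit of 1
and a chi square of 1; division-free paths guard empty histograms and
zero denominators with informative errors.

## Known limitations

* The GED kernel is an operationalization, not the vendor's algorithm;
  absolute GED values are only meaningful relative to the kernel
  configuration used for training and prediction together (both sides
  always read it from the same model configuration).
* "Average chi square" and "model fit" implement documented semantics
  ("closer to 1 is better") rather than a disclosed formula.
* The out-of-field band is a population mean/SD model: its ±1 SD
  nominal coverage (~68%) holds for cohorts resembling the training
  population and says nothing about an individual geometric outlier.
* Priorities and objective margins are template data with sensible
  defaults, not learned quantities.
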
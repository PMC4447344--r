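---
title: "Probability-based design spaces by Monte-Carlo model regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probability-based design spaces by Monte-Carlo model regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdspace)
```

## The problem

A pharmaceutical process step — here the packaged worked example, the hot-water
extraction of mixed Danshen and Honghua that feeds Danhong injection — is
characterised by a handful of controllable critical process parameters (CPPs)
and judged by measurable critical quality attributes (CQAs) that must fall
inside registered limits. A *design space* in the probability-based sense is
the region of CPP settings where the probability that **all** CQAs jointly meet
their limits exceeds an acceptance level (0.95 by default). A point estimate of
the response surface cannot express that probability; some account of model and
measurement uncertainty is needed. This package propagates measurement
uncertainty by brute force: it regenerates the experimental data many times
from an estimated noise model, refits the entire model-selection-plus-OLS
pipeline on every regenerated data set, and counts how often the resulting
model ensemble predicts all CQAs within their limits at each grid point of the
factor space.

## Response-surface models

All modelling is on the coded factor scale. Each factor is coded affinely,

$$x = \frac{u - c}{h},$$

with centre $c$ the midpoint of the extreme levels and half-range $h$ their
half-distance, so the design's extremes map to $\pm 1$. Coding is affine even
when a factor's middle level is off-centre (extraction time 0.5/1/2 h has
centre 1.25 h, so 1 h codes to $-1/3$): only the affine map keeps the inverse
exact and matches the worked example's published coding. The extraction number
is carried as a real in the models but flagged *discrete*: design-space slices
are computed at its coded levels only.

For one CQA $Y$ and three coded factors, the candidate model is the full
quadratic

$$Y = a_0 + a_1 X_1 + a_2 X_2 + a_3 X_3 + a_4 X_1X_2 + a_5 X_1X_3 +
      a_6 X_2X_3 + a_7 X_1^2 + a_8 X_2^2 + a_9 X_3^2,$$

fitted by ordinary least squares. Per-coefficient significance is the
two-sided $t$ test with residual degrees of freedom.

### Stepwise term selection

Terms are selected by the classical bidirectional p-value procedure, starting
from the intercept-only model. Each sweep:

1. **add** the excluded candidate with the smallest p-value (as tested in the
   enlarged model), if that p-value is below `alpha_enter`;
2. **remove** the included term with the largest p-value, if it exceeds
   `alpha_remove`.

Sweeps repeat until a full sweep changes nothing. The two levels are equal by
default (`alpha = 0.35`, the optimized value for the worked example; 0.15 is
used in the stability study). Design choices worth making explicit:

* *No hierarchy enforcement.* A quadratic or interaction term may survive while
  its parent linear term is dropped — the worked example's published
  hydroxysafflor-yellow-A model keeps $X_1^2$ without $X_1$, so hierarchy is
  demonstrably not enforced by the original analysis either.
* *Tie-breaking.* Equal p-values admit the earlier term in the canonical order
  (linear, interactions, quadratics) and remove the later one, making the
  procedure deterministic given the data.
* *Degenerate results are legal.* Under heavy noise and small `alpha` the
  selection may retain nothing; the intercept-only model predicts a constant
  and still contributes to ensemble probabilities — excluding such fits would
  bias them.
* *Exact fits.* When a candidate set interpolates the data exactly the residual
  variance underflows and $t$ statistics become 0/0. The fitting kernel detects
  a numerically-zero SSE (relative to the response scale) and assigns p-value 0
  to clearly non-zero coefficients and 1 to zero ones, which is the correct
  limit of the test.
* A sweep limit (50) guards against cycling; hitting it raises an error naming
  the terms involved rather than returning silently.

### Model-quality criteria

The criteria reported per fit, with $n$ runs and $p$ coefficients including the
intercept, are the standard definitions:
$R^2 = 1 - SSE/SST$ (SST about the mean), $R^2_{adj} = 1 -
\frac{SSE/(n-p)}{SST/(n-1)}$, $R^2_{pred} = 1 - PRESS/SST$ with PRESS computed
through the hat matrix ($e_i/(1-h_{ii})$, identical to explicit leave-one-out
refitting, which the test suite verifies), $AIC = n\ln(SSE/n) + 2p$ and
$BIC = n\ln(SSE/n) + p\ln n$. The uncorrected AIC is used; with $n = 15$ the
small-sample correction would shift absolute values considerably, but all
conclusions drawn from the criteria here are about trends across the stepwise
significance level, which are insensitive to the variant. Under these
definitions, averaging criteria over 1000 regenerated data sets per
significance level on the worked example, mean $R^2$ increases monotonically
with the level, mean $R^2_{adj}$ and AIC turn over between 0.3 and 0.4
(supporting the 0.35 default), while mean BIC turns slightly earlier (0.25) and
mean $R^2_{pred}$ earlier still — a consequence of their stronger sparsity
preference at $n = 15$, not of the implementation.

## The noise model

The replicated centre point anchors all uncertainty. Per CQA, the sample mean
and SD ($n-1$ denominator) of the replicate group give the centre mean and SD;
their ratio is the relative standard deviation (RSD). For the worked example
the centre RSDs are 2.2–8.1% depending on the CQA. Every run is then assumed to
share its CQA's RSD: regeneration draws each response independently with

* replicate-group runs: mean = centre mean, SD = centre SD (the centre point is
  one distribution; its replicates are exchangeable draws from it);
* all other runs: mean = measured value, SD = RSD × measured value.

Four distribution families are supported; in each, the *distribution's* mean
and SD are moment-matched to the targets:

| family | transform | matching |
|---|---|---|
| `normal` | — | identity |
| `lognormal` | $\log X$ normal | closed form: $\sigma^2 = \log(1+cv^2)$ |
| `sqrt-normal` | $\sqrt X$ normal | closed form via $E X = \mu^2+\sigma^2$, $\mathrm{Var}\,X = 4\mu^2\sigma^2+2\sigma^4$ |
| `reciprocal-normal` | $1/X$ normal | 1-d root search on numerically integrated moments |

The reciprocal family's coefficient of variation is scale-free in the CV of the
underlying normal, so a single `uniroot` on the CV followed by a location
rescale suffices; moments are integrated over ±8 SD, which requires target CVs
below 0.1 (well above the RSDs seen in replicated designs of this kind).
Normal-family draws are kept even if negative — at single-digit RSDs such draws
are vanishingly rare and truncation would bias the matched moments; the
transformed families are positive by construction.

## Ensemble, probability map, design space

One *simulation* regenerates the full response table and stepwise-refits every
CQA. `n_sims` simulations (default 10000) form the ensemble; a simulation
whose selection fails is dropped and counted, and more than 1% failures abort
the run. Predictions are model means — no residual noise is re-added at
prediction time, so cell probabilities quantify model uncertainty propagated
from the data, and all six CQA models of a given simulation are evaluated
jointly (the same regenerated data set either passes or fails a grid point).

The probability map evaluates every simulation's models on a regular grid over
the coded $[-1,1]^2$ of the two free factors (both endpoints included;
`round(2/step) + 1` points per axis, 201 × 201 at the default step 0.01), the
discrete factor fixed at a coded slice. Cell probabilities are exact empirical
fractions of simulations passing all limits — the test suite checks cells
bit-for-bit against a brute-force counting loop.

The design space is the cell set with probability ≥ threshold. Its
*dimensionless size* (DSS) is the fraction of grid cells in the mask over the
coded slice — a normalization chosen here because the original study never
defines its own; the stability diagnostic RSDDSS (below) is invariant to that
constant, so only RSDDSS is compared across implementations, not absolute DSS.
For stability metrics the whole computation (regeneration, refitting, map,
mask) is repeated `n_repeats` times (default 10) with independent sub-seeds
derived from the master seed: ADSS is the mean DSS and RSDDSS the relative
standard deviation in percent. An RSDDSS estimate from 10 repeats is itself an
SD over 10 draws and carries roughly 25% relative sampling error — single
estimates near a stated bound should be interpreted (and are tested)
seed-averaged.

Randomness follows one contract: every user-facing computation takes a master
seed, derives any sub-stream seeds deterministically from it, and identical
configuration plus seed yields byte-identical outputs (CSV numerics are
written at 6 significant digits to keep hashes platform-stable; JSON keeps
full precision).

## Yields from raw measurements

The CQAs are per-gram yields, `content × extract mass / basis mass`. Different
CQAs are conventionally expressed against different raw-material bases (each
ingredient against the herb it originates from, dry matter against total
material); the basis is carried as CQA metadata and resolved by name. This
module is off the modelling critical path — the packaged design table already
stores yields — and exists so raw-measurement inputs are supported.

## The synthetic generator

`generate_synthetic()` emulates the structure of the worked example: the same
15-run layout (or any supplied coded layout), responses from a known quadratic
surface, and multiplicative normal noise of stated RSD — mirroring the
RSD-proportional noise model above, with non-positive draws redrawn (yields are
positive). Defaults follow the study's conditions: 5% RSD, three centre
replicates in the layout. What it deliberately does not emulate: non-quadratic
curvature, run-order drift, correlated errors between CQAs, or heteroscedastic
structure beyond RSD-proportionality. Passing recovery tests on synthetic data
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not robustness of the method on real extraction data.

## Problem sizes and tolerances in the shipped checks

The test suite exercises the full study conditions where the checked claim
depends on them (10000 simulations, step 0.01, 10 repeats for the stability
claim; 10000 simulations and step 0.04 grids for the family comparison, where
the size statistic is step-insensitive) and small configurations (50–1000
simulations, coarse grids) where the property checked is exact by construction
— bit-exact probability fractions, determinism, oracle equivalences at 1e-8,
coding round trips at 1e-12. Stochastic claims are asserted on means over
three master seeds with paired draws where the comparison is between
conditions.

## Known limitations

* Only the centre point's RSD informs the noise model; if those three
  replicates happen to misestimate the true dispersion, the design space moves
  accordingly. Replicating more conditions is the remedy, not a calculation
  option.
* Probabilities cover model uncertainty propagated from measurement noise, not
  lack-of-fit of the quadratic form itself.
* Grids and slices: the map is two-dimensional per slice; factors beyond three
  work in the models, but design-space extraction expects exactly two free
  factors per slice.
* ADSS depends on the mask-fraction normalization and is not comparable across
  packages that normalize differently; RSDDSS is.
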
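# mcdspace

Probability-based design spaces for designed process experiments by
Monte-Carlo simulation.

## What problem this solves, and for whom

Process developers working under quality-by-design identify critical process
parameters (CPPs), run a small designed experiment, and model each critical
quality attribute (CQA) as a quadratic response surface in coded factors,

    Y = a0 + a1*X1 + a2*X2 + a3*X3 + a4*X1X2 + a5*X1X3 + a6*X2X3
          + a7*X1^2 + a8*X2^2 + a9*X3^2,

with insignificant terms removed by bidirectional p-value stepwise
regression. A point-estimate model cannot say how *sure* one is that an
operating point meets all specifications. `mcdspace` answers that with a
Monte-Carlo approach: estimate per-CQA measurement noise from the design's
centre replicates (RSD of the replicate group, propagated proportionally to
every run), regenerate the whole response table thousands of times from a
configurable distribution family (normal, lognormal, square-root-normal,
reciprocal-normal, each moment-matched to the target mean and SD), refit the
stepwise-selected models on every regenerated table, and count — per grid
point of the factor space — the fraction of model sets whose predictions
jointly satisfy every CQA limit. The *design space* is the region where that
probability is at least a threshold (0.95 by default); its dimensionless size
(DSS), repeat-averaged size (ADSS) and relative standard deviation over
repeats (RSDDSS, a stability diagnostic for the simulation settings) are
reported alongside the map.

The 15-run, three-CPP, six-CQA Danhong-injection extraction study ships as
the built-in worked example (`danhong_fixture()`), complete with factor
coding, CQA acceptance limits, and the published per-CQA term sets
(`danhong_term_sets()`).

## Worked example

```r
library(mcdspace)
dh <- danhong_fixture()

# stepwise model for one CQA at the optimized significance level
stepwise_select(dh$design, "danshensu", alpha_enter = 0.35)
#> Quadratic response-surface fit: danshensu (coded units)
#>                       (Intercept)                   extraction_time
#>                            2.1658                            1.0119
#>                          wm_ratio                 extraction_number
#>                            0.1533                            0.7951
#> extraction_time:extraction_number        wm_ratio:extraction_number
#>                            0.3728                           -0.0655
#>               extraction_number^2
#>                           -0.2742
#> R2 0.9928  R2adj 0.9875  R2pred 0.9692
```

The selected terms and coefficients match the study's published Danshensu
model (intercept 2.166, time coefficient 1.012, R² 0.993 at the printed
precision). Verifying a candidate operating point — 1.6 h extraction,
8.3 g/g water-to-material ratio, 2 extractions — against all six CQA limits:

```r
noise <- estimate_noise(dh$design)        # centre-replicate RSDs, 2.2-8.1%
ens <- fit_ensemble(dh$design, noise, sim_config(n_sims = 2000, seed = 1))
verify_point(ens, c(extraction_time = 1.6, wm_ratio = 8.3,
                    extraction_number = 2), dh$cqas)
#> Operating-point verification at extraction_time = 1.6, wm_ratio = 8.3, extraction_number = 2
#>                      cqa predicted ensemble_mean lower upper within
#>                danshensu     2.661         2.662   2.0   3.8    Yes
#>  hydroxysafflor_yellow_A     6.264         6.308   5.1   7.6    Yes
#>          rosmarinic_acid     2.063         2.069   1.8   2.2    Yes
#>        lithospermic_acid     2.435         2.435   2.1   2.6    Yes
#>       salvianolic_acid_B    37.338        37.257  36.0  45.0    Yes
#>               dry_matter   490.454       491.328 400.0 550.0    Yes
#> Joint probability of meeting all limits: 0.9940 (2000 sims)
```

Every point estimate is inside its limits and 99.4% of the 2000 regenerated
model sets agree — this operating point sits comfortably in the design
space. The full design-space computation with stability metrics (here at a
reduced size; defaults are 10000 simulations, step 0.01, 10 repeats):

```r
ds <- design_space(dh$design, dh$cqas,
                   cfg = sim_config(n_sims = 2000, step_length = 0.02,
                                    n_repeats = 3, seed = 1),
                   slice = c(extraction_number = 0))  # 2 extractions
ds
#> Design space at threshold 0.95
#>   DSS per repeat: 0.2308, 0.2278, 0.227
#>   ADSS 0.2285  RSDDSS 0.859%
plot(ds)   # probability map with the 0.95 iso-contour
```

About 23% of the coded time × ratio plane at 2 extractions qualifies; the
repeat-to-repeat spread (RSDDSS) shrinks as `n_sims` grows, which is how the
simulation number is chosen. A command-line front end (`exec/mcdspace`) with
`fit`, `designspace`, `verify` and `synth` subcommands wraps the same
functions for shell use, writing the probability map as CSV, metrics as JSON
and an optional PNG contour.

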
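# migvar

Variance decomposition and batch-effect removal for multi-site
high-content cell-migration imaging.

When several laboratories run a nominally identical live-cell migration
assay, the resulting feature tables nest: laboratories contain persons,
persons run independent experiments, experiments hold technical
replicates per treatment condition, replicates hold cells, and each cell
is measured over many time points.  `migvar` answers three questions
about such data:

1. **Where does the variance come from?**  A from-scratch
   maximum-likelihood linear mixed-effects model with nested random
   intercepts,

   *y* = β₀ + δ·1[treated] + u_lab + u_person + u_exp + u_rep + u_cell + ε,

   u_ℓ ~ N(0, σ²_ℓ), ε ~ N(0, σ²₀), estimates one variance per design
   level plus the temporal residual, and splits the total into technical
   (replicate, experiment, person, laboratory) and biological (cell,
   temporal) shares.  The likelihood is evaluated in O(n) by collapsing
   sufficient statistics up the nesting tree; fixed effects are profiled
   out; boundary components are reported as exactly zero.

2. **How does variability accumulate?**  Cumulative-variability curves
   enumerate every consistent subdataset with k = 2 or 3 units at one
   level (sharing a single origin above, complete below) and report the
   variance of technical-replicate means, against a label-randomized flat
   control.

3. **Can data from different sites be combined?**  Batch-effect removal
   subtracts each observation's predicted technical random intercepts
   (BLUPs from a sparse Henderson solve) while keeping fixed effects and
   biological variation intact — for 2D feature tables and for 3D
   spheroid-invasion distances (laboratory/experiment/replicate/spheroid
   hierarchy, collagen condition as fixed effect).

Around this core the package provides: a synthetic-data generator that
reproduces the multi-site study design (3 labs × 3 persons × 3
experiments × 2 conditions × 3 replicates, ~50 cells, 72 time points at
5-min intervals) with exact ground truth; extraction of 18 per-cell
features from labeled mask movies (15 morphology/dynamics variables plus
protrusion, retraction and short-lived region areas from three-frame mask
differencing); nucleus-distance cell tracking; trajectory QC, window-9
smoothing, instantaneous cell speed (ICS), z-scoring and PCA; and 3D
spheroid tools (circumsphere through four annotated points, signed
migration distances, detection precision/recall).

## Worked example

```r
library(migvar)

sim <- simulate_migration_study(design_spec(n_cells = 10, n_timepoints = 24),
                                generative_params(seed = 42))
fit <- fit_nested_lme(sim$table, "ics", fixed = "condition")
fit
#> Nested random-intercept mixed model (ML)
#>   response: ics, n = 38880
#>   beta0 = 9.12528, delta(condition) = 3.00377
#>   variance components:
#>     lab        3.33289
#>     person     1.60778
#>     experiment 0.348352
#>     replicate  0.308996
#>     cell       1.94765
#>     residual   2.03399
#>   log-likelihood: -71655.2
```

The generative truth here was β₀ = 10, δ = 3 and σ² = (4, 1, 0.5, 0.25,
2, 2): the treatment effect is recovered to 0.1% and each variance
component to within its sampling spread (with only three laboratories,
σ²_lab is the noisiest estimate).  The variance table classifies the
sources:

```r
decompose_variance(fit)
#> Variance components per feature
#>  feature      level variance   share
#>      ics        lab   3.3329 0.34791
#>      ics     person   1.6078 0.16783
#>      ics experiment   0.3484 0.03636
#>      ics  replicate   0.3090 0.03226
#>      ics       cell   1.9477 0.20331
#>      ics   residual   2.0340 0.21232
#> technical share: ics=0.584 (median 0.584)
```

Batch correction strips the technical components while preserving the
biological ones and the treatment effect:

```r
corrected <- remove_batch_effects(sim$table, fit)
refit <- fit_nested_lme(corrected, "ics", fixed = "condition")
round(refit$sigma2, 4)
#>        lab     person experiment  replicate       cell   residual
#>     0.0000     0.0000     0.0000     0.0000     1.8134     2.0340
```

Cumulative variability shows the characteristic jump when laboratories
are combined (lab-dominant generative condition):

```r
cumulative_level_means(cumulative_variability(sim$table, "ics"))
#>        level mean_variance
#> 1  replicate     0.5649189
#> 2 experiment     0.8453090
#> 3     person     2.0342877
#> 4        lab     5.1574134
```

The same machinery runs end to end from a YAML configuration via
`run_pipeline()` (stages: simulate, extract, preprocess, fit, decompose,
cumulative, correct, spheroid, report), or from the shell through the
thin wrapper in `inst/scripts/run_pipeline.R`.

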
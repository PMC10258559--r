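---
title: "Quantifying and removing multi-site variability in cell-migration imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and removing multi-site variability in cell-migration imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migvar)
```

## The problem

High-content live-cell imaging of migrating cells produces feature tables
— per-cell, per-time-point measurements of morphology and motion — whose
values reflect not only biology but also where, by whom and when the
experiment was performed.  When several laboratories run a nominally
identical assay, the data nest naturally: laboratories contain persons,
persons run independent experiments, experiments contain technical
replicates per treatment condition, replicates contain cells, and each
cell is observed over many time points.  `migvar` quantifies how much
variance each of these levels contributes, identifies how variability
accumulates as a hypothetical study grows in complexity, and removes the
technical part of the variance so that perturbation effects measured in
different laboratories can be compared directly.  A 3D companion workflow
does the same for spheroid invasion distances measured at two sites.

## The model

For a feature $y$ observed on the nested design, the package fits

$$y_{lpecrt} = \beta_0 + \delta\,\mathbb{1}[\text{treated}]
  + u^{lab}_l + u^{person}_{lp} + u^{exp}_{lpe} + u^{rep}_{lper}
  + u^{cell}_{lperc} + \varepsilon_{lpecrt},$$

where each random intercept is drawn from a centred normal with a
level-specific variance $\sigma^2_\ell$ and the residual
$\varepsilon \sim N(0, \sigma^2_0)$ captures frame-to-frame (temporal)
variation within a cell.  All parameters are estimated by maximum
likelihood; REML is available behind a flag for sensitivity analysis but
ML is the method of record.  Variance components are classified as
*technical* (replicate, experiment, person, laboratory) or *biological*
(cell identity and the temporal residual); their shares of the total are
the main descriptive output (`decompose_variance()`).

### Likelihood evaluation

Because the levels are strictly nested, the marginal covariance never has
to be formed.  Each unit's observations are collapsed into seven
sufficient statistics ($1'V^{-1}1$, $X'V^{-1}1$, $X'V^{-1}y$,
$X'V^{-1}X$, $y'V^{-1}y$, $\log|V|$), and absorbing a unit's intercept
variance $\tau^2$ is a rank-one Woodbury update of those statistics.  One
likelihood evaluation therefore costs $O(n)$ and, because the
observation-to-cell aggregation is linear in $1/\sigma^2_0$, it is
performed once per fit rather than once per evaluation.  Fixed effects
are profiled out in closed form.  The test suite verifies the collapsed
evaluation against an explicit dense-covariance computation to $10^{-10}$
and the full fit against both a dense maximum-likelihood oracle and
`lme4` (the latter agreeing in log-likelihood, fixed effects, variance
components and BLUPs).

### Optimization and boundaries

Variances are optimized on the log scale with a quasi-Newton method
(`nlminb`/PORT; up to 500 iterations, relative tolerance $10^{-12}$),
started from method-of-moments values derived from between-unit variances
of OLS residuals, floored to keep the parameterization finite.  Variance
components are non-negative by construction; estimates that drift to the
edge of the box are candidates for the boundary.  Each candidate (smallest
first) is refitted with that component fixed at exactly zero and the zero
is accepted only when the profiled log-likelihood changes by less than
$10^{-6}$ — so a component reported as 0 is exactly 0, never a small
positive artifact of the parameterization.  If the response is exactly
linear in the fixed effects (no residual spread at all), the fit
short-circuits to the degenerate solution with all variances zero.

### Predicted random intercepts

`predict_random_intercepts()` solves the mixed-model (Henderson)
equations at the ML estimates with a sparse Cholesky factorization
(`Matrix`), giving empirical-Bayes (BLUP) predictions for every unit.
Levels with a zero variance component receive exactly zero.  For a single
balanced level this reproduces the textbook shrinkage
$n\sigma^2/(n\sigma^2 + \sigma_0^2)\,(\bar y_u - \bar y)$.  One property
worth knowing: in a shallow hierarchy the mean of a parent's children is
absorbed by the parent, so BLUPs at, say, the experiment level estimate
the *within-person-centred* experiment intercepts.  This is a feature of
the model, not of the implementation — `lme4::ranef` behaves identically.

## Batch-effect removal

The correction subtracts from every observation the BLUPs of its
technical units:

$$y^{corr} = y - (\hat u_{lab} + \hat u_{person} + \hat u_{exp}
 + \hat u_{rep}).$$

The model must be fitted on the complete two-condition dataset with the
condition as a fixed effect, so that the treatment contrast lives in
$\delta$ and is untouched by the subtraction; the package refuses to
correct a two-condition table with a condition-free model.  Cell-level
intercepts and the temporal residual are deliberately retained: they are
the biological signal, and subtracting the observation-level residual
would annihilate all within-condition variation.  Because only random
intercepts are removed and they average to approximately zero within each
level, no re-addition of fixed effects is needed and the grand mean is
preserved.  The 3D variant (`correct_3d()`) uses the hierarchy
laboratory / experiment / replicate / spheroid with the collagen
concentration as the fixed effect and corrects the first three levels.

## Cumulative variability

`cumulative_variability()` emulates designs of growing complexity: $k$
units (2 or 3) chosen at one level — technical replicate, experiment,
person or laboratory — sharing one complete path above them and carrying
everything below them.  Subdatasets mixing units with different origins
in the next-higher level are never formed.  The per-subdataset statistic
is the sample variance ($n-1$) of per-technical-replicate mean feature
values; the level curve is its mean over all subdatasets and
multiplicities.  The statistic acts on replicate means because the
technical replicate is the design's atomic unit, and spread among
replicate means is exactly what grows as higher levels are allowed to
vary; the reported distribution-plus-mean mirrors how such curves are
summarized graphically.  The negative control permutes the replicate
means across the whole design (preserving within-replicate structure)
before the same enumeration, which flattens the curve.  Enumeration
operates on one condition at a time, since mixing conditions would
confound treatment with technical spread.

## Feature extraction from mask movies

The extractor consumes labeled cell- and nucleus-mask movies (one stable
positive label per cell, shared between the two channels) and emits 18
variables per cell and frame: 15 segmentation-derived measurements —
cell area, perimeter, form factor $4\pi A/P^2$, eccentricity, solidity,
extent, major/minor axis lengths, equivalent diameter, nucleus area,
nucleus perimeter, nucleus form factor, nucleus-to-cell area ratio,
cell-centroid speed, nucleus–cell centroid offset — plus the three
mask-differencing areas: protrusions (pixels present now, absent in the
previous frame), retractions (present now, absent in the next) and
short-lived regions (present only now, i.e. a lifetime under one frame
interval).  The 15-variable list is this package's concrete choice of
standard morphology-profiler measurements; published studies rarely
enumerate theirs in machine-readable form.

Conventions, stated once and used everywhere: pixel centres at integer
coordinates with the origin at the top-left pixel, x rightward, y
downward; 8-connectivity; physical units via the pixel size (µm/pixel).
The perimeter is the Vossepoel–Smeulders corrected length of the outer
Moore boundary chain, $0.980\,N_{even} + 1.406\,N_{odd} -
0.091\,N_{corner}$, accurate to about 1% for smooth outlines (a
rasterized disk of radius 20 px has form factor ≥ 0.95); an isolated
pixel is assigned its crack length 4, and inner (hole) boundaries are not
traced — the synthetic generator produces simply connected cells.  Form
factor is clamped at 1 (tiny objects can exceed it under any discrete
perimeter estimator).  Solidity uses the pixelated convex hull (pixel
centres covered by the hull polygon), guaranteeing values in (0, 1].
Dynamic-region areas are per-frame totals per cell; individual regions
are not tracked.  At movie edges the undefined member of the triple is
reported missing, and a label present in neither neighbouring frame is a
whole-cell appearance — excluded and flagged rather than scored.

Tracking links nucleus centroids frame to frame, greedily by increasing
distance with ties broken by lower label id, never beyond the gate
distance; a long jump ends the track and starts a new one.  On
well-separated synthetic data this matches brute-force optimal
assignment, which the tests verify.

## Trajectory preprocessing

Quality control removes, in order: merged trajectories (two nucleus
tracks on one cell label in a frame — both tracks dropped), duplicated
trajectories (two tracks sharing at least half of their identical
centroid records — the later-sorted track dropped), oversized cells
(per-cell mean area above $Q_3 + 1.5\,\mathrm{IQR}$ of all per-cell mean
areas, quantiles by linear interpolation / type 7), and undersized nuclei
(below 100 µm², observation-wise).  The area rule is re-applied until no
cell exceeds the recomputed threshold; a single pass would not be
idempotent because removing the tail shifts the quantiles, and an
idempotent filter is easier to reason about in pipelines.  A removal
count per rule and the thresholds used are returned alongside the table.

Trajectories are smoothed with a centred rolling mean of window 9
(frames); at the ends the window shrinks symmetrically to the largest odd
size that fits, so constant and linear paths pass through unchanged in
the interior.  The instantaneous cell speed (ICS) is the Euclidean
displacement of the smoothed positions per interval, in µm/min, assigned
to the later frame — a 73-frame movie (6 h at 5-min intervals) yields
exactly 72 ICS values per cell.  Features are z-scored over all pooled
observations (control and treated together, matching how the joint PCA
space is used downstream; zero-variance features are dropped with a
warning), and PCA is computed on the standardized table with components
ordered by explained variance and signs fixed so the largest-magnitude
loading is positive.

## The synthetic-data generator

The generator is first-class, tested code and defines the study
conditions everything else is validated under:

* **Design**: 3 laboratories × 3 persons × 3 experiments × 2 conditions
  (control, treated) × 3 technical replicates, 50 cells per replicate, 72
  time points at 5-min intervals.  These are the reference design's
  printed values and the `design_spec()` defaults.
* **Feature model**: Gaussian random intercepts drawn independently per
  unit and level, i.i.d. Gaussian residuals per time point, and an
  additive treatment effect.  The identity
  $y = \beta_0 + \delta + u_L + u_P + u_E + u_R + u_C + \varepsilon$
  holds exactly (bit-for-bit) for every observation, which is what lets
  the estimator, the correction and the cumulative curves be tested
  against known truth.
* **Default parameters**: $\sigma^2 = (4, 1, 0.5, 0.25, 2, 2)$ for
  (lab, person, experiment, replicate, cell, residual), $\delta = 3$,
  $\beta_0 = 10$.  The ordering — laboratory dominant among technical
  sources, substantial cell and temporal variability — mirrors what
  multi-site imaging studies report; the absolute values are chosen once
  as a clear, lab-dominant reference condition and are not tuned.
* **Mask movies**: cells are rasterized disks with scripted per-frame
  displacements and scripted boundary "bumps" (extra area with a defined
  first frame and lifetime), rendered by pixel-centre-in-shape tests with
  stable 16-bit labels; nuclei are concentric disks at a fixed fraction
  (default 0.4) of the cell radius.  Scripts that would overlap cells or
  touch the image border are rejected.  The recorded ground truth (areas,
  centroids, speeds, protrusion/retraction/short-lived pixel counts) is
  taken from the rendered pixel sets, so the extractor can be required to
  reproduce it exactly.
* **3D scenes**: four core-surface points are a randomly rotated regular
  tetrahedron lying exactly on the core sphere, so the circumsphere
  construction must recover centre and radius to numerical precision;
  nuclei sit at recorded signed radial offsets.  The simulated invasion
  study (2 laboratories × 3 experiments × 2 collagen conditions × 3
  replicates × 3 spheroids, 30 nuclei each) draws per-nucleus distances
  from the same nested-intercept machinery (means 80 µm at 2.5 mg/ml and
  40 µm at 6 mg/ml, within-spheroid SD 30 µm, level variances 100 / 25 /
  9 / 16 µm²) and routes every value through the geometry pipeline.

What the generator deliberately does not emulate: fluorescence
intensities, segmentation errors, cell division, collisions or contact,
temporal autocorrelation of the residual, cross-feature correlation, and
non-Gaussian feature distributions.  Passing tests therefore demonstrate
correctness of the estimators and operators under the stated model — not
robustness to segmentation noise or to misspecified distributions in
real microscopy data.

## Numerical choices and degenerate inputs

* Sphere through four points: solved from the 3×3 linear system of
  pairwise equidistance; a reciprocal condition number below $10^{-12}$
  (near-coplanar points) is a geometry error rather than a garbage
  sphere.
* Migration distance is signed ($\lVert x - c\rVert - r$; negative inside
  the core); downstream summaries may clamp at zero if an unsigned
  reading is wanted.
* Detection scoring uses one-to-one greedy matching by increasing
  distance within a configurable gate (default 5 µm), ties to lower
  indices; precision is undefined (missing) for an empty segmentation,
  with recall 0.
* All stochastic stages derive their streams from one integer seed via a
  deterministic string-hash split, so any stage can be regenerated in
  isolation and identical configurations produce byte-identical outputs.
* Test and acceptance problem sizes: the estimator studies run the full
  design scaled to 10 cells × 24 time points (38,880 observations per
  run, 20 runs), oracle equivalence uses 50 random datasets of at most 60
  observations, the mask-differencing sweep uses 100 random 3-cell,
  4-frame movies, and cumulative-variability curves use 5 cells × 6 time
  points over 20 runs.  These sizes give stable Monte-Carlo summaries
  while keeping a full validation run in the tens of seconds on one CPU.

## Known limitations

* Only strictly nested designs are supported — no crossed random effects,
  random slopes, or non-Gaussian responses; variance components are point
  estimates without confidence intervals.
* ML variance estimates at levels with very few units (three
  laboratories) are biased low in any single study; the simulation tests
  therefore compare Monte-Carlo means across repeated runs rather than
  single-run values.
* The perimeter estimator targets smooth boundaries; it underestimates
  for few-pixel regions, which sit below the nucleus-area QC threshold in
  practice.
* The batch correction is the random-intercept subtraction described
  above; alternative correction families (location–scale matching,
  empirical-Bayes shrinkage across features) are out of scope.
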
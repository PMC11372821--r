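---
title: "Methods: ensemble habitat models, niche hypervolumes and protection gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble habitat models, niche hypervolumes and protection gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical
conventions that make the pipeline deterministic and testable.

## The study system and the grid

The pipeline targets a marine species occupying a tropical window
(by default 90–140° E, 11° S–15° N) with two genetically distinct
populations — an Eastern Indian Ocean–South China Sea (EIOS) population
and a Western Pacific–Indonesia (WPI) population — separated by a
north–south boundary polyline through the Makassar Strait / Indonesian
Throughflow corridor. All rasters share one regular WGS84 grid,
registered by cell edges, at 5 arc-minutes (≈ 9.2 km at the equator) by
default.

Grid conventions, chosen once and used everywhere:

* row 1 is the northernmost row; cells are half-open
  `[edge, edge + resolution)`, so a point exactly on an interior boundary
  belongs to the higher-index (east/south) cell. This makes thinning and
  extraction deterministic.
* cell areas use the spherical-cap formula
  \(A = R^2\,\Delta\lambda\,(\sin\varphi_t - \sin\varphi_b)\) with
  \(R = 6371\) km fixed. Over a 26°-wide tropical window cell areas vary
  by a few percent, enough to matter for km² bookkeeping, and a stated
  constant keeps tests exact. No projection is used; areas are geodesic
  by construction.
* points exactly on the population boundary are assigned to the western
  (EIOS) side — an arbitrary but fixed and logged tie-break.

Rasters travel as plain-text ESRI ASCII grids (single band, explicit
nodata) written at full `%.17g` precision so a write→read round trip is
bit-exact on valid cells; vector data (boundary, MPA polygons) travel as
GeoJSON.

## Synthetic data: what it emulates, and what it does not

Every stage is exercised on generated inputs with the statistical
structure the analysis assumes:

* **Predictors.** Nine layers named for the canonical variable set
  (current velocity, salinity, temperature mean, temperature range,
  depth, distance to shore, dissolved oxygen, light at bottom,
  phytoplankton). Each is white noise smoothed by a separable Gaussian
  kernel of scale `autocorr_cells` (default 6 cells ≈ 55 km, a mesoscale
  correlation length) and mapped affinely into a plausible range, e.g.
  temperature ≈ 20–31 °C. The land/sea mask is the sign of the synthetic
  depth field (≈ 84% sea), which keeps "non-marine record" filtering
  testable.
* **Niches.** A population's suitability is a product of independent
  Gaussian terms — smooth, unimodal, with an analytically known optimum,
  which is what makes parameter-recovery tests possible. The two default
  populations differ in temperature and salinity optima (tolerances
  1.5 °C and 1.0 salinity units), separated by 2 tolerance-standardised
  units. Their temperature optima sit at or below the centre of the
  current temperature field: the species is simulated at its thermal
  optimum today, so *any* scenario warming pushes occupied cells past the
  optimum and suitable area shrinks monotonically with warming — the
  regime the projected range losses represent.
* **Scenarios.** Only the four dynamic layers change (temperature mean
  and range, salinity, current velocity); static layers are bit-identical
  by contract. The four presets warm by +0.6, +0.9, +1.4 and +3.0 °C
  (2050s/2100s × RCP 2.6/RCP 8.5), with slight freshening and a widening
  seasonal range.
* **Occurrences.** Presences are sea cells drawn with probability
  proportional to true suitability, placed at cell centres. Default
  sampling is with replacement — repeat observations of good habitat that
  grid thinning later collapses, as with real aggregated databases; a
  `distinct` mode caps at one record per cell and errors when
  oversubscribed.
* **MPAs.** Axis-aligned rectangles centred on random sea cells, with
  jittered sizes and a bisection on a common scale factor until realised
  sea coverage is within 5% relative of the target (default 16%, echoing
  the real protection level of the study region).

Deliberately *not* emulated: realistic oceanography (fields are
independent across variables; distance-to-shore is a smooth field, not a
true distance transform), spatial sampling bias, observation error in
coordinates, and coastline geometry. Passing tests therefore demonstrate
that the machinery recovers known truth under the model's own
assumptions — not that any particular real dataset satisfies them.

## Occurrence preparation

Cleaning removes records with missing coordinates, collapses exact
duplicate coordinates (first record wins, order stable), and drops
records outside the extent or on land. Thinning keeps at most one
presence per grid cell — the deterministic cell-deduplication reading of
"one record per 5′ cell" — and is idempotent. Pseudo-absences are drawn
uniformly *without* replacement, in equal number to the presences, from
sea cells that contain no presence **and** lie outside the presences'
per-variable [min, max] environmental envelope; if too few such cells
exist the envelope rule is relaxed to presence-free cells with a logged
warning. The envelope rule is the simplest testable operationalisation of
"conditions where the species did not occur"; a `cells_only` switch
disables it.

## Collinearity screening and PCA

The screen is greedy and two-staged: while any retained pair has
|Pearson r| ≥ 0.7, drop from the worst pair the variable with the larger
mean absolute correlation; then while any variance inflation factor
(VIF = 1/(1 − R²) of a variable regressed on the rest) reaches 10, drop
the largest. The thresholds are the conventional ones; the elimination
*order* is a package choice, since thresholds alone do not determine one.
Constant columns (undefined VIF) are dropped up front with a warning.

PCA standardises variables first (the units are incommensurable) and
fixes each component's sign so its largest-magnitude loading is positive,
making scores reproducible across row orders and platforms. The niche
analysis retains k = 4 components by default and fits one common space on
the pooled presences of both populations, so the two populations are
compared in the same coordinates; a switch allows fitting on all sea
cells instead.

## Niche hypervolumes and the difference decomposition

A population's realized niche is modelled as the region of PCA space
where a Gaussian product-kernel density estimate of its occurrence scores
exceeds a threshold. Settings, all configurable:

* **bandwidth** — per-dimension Silverman rule,
  \(h_j = \sigma_j (4/((d+2)n))^{1/(d+4)}\);
* **inclusion quantile** (default 0.95) — the threshold is the density
  value above which 95% of the training points lie;
* **volume** — uniform Monte-Carlo sampling over the training bounding
  box expanded by 3 bandwidths; the accepted draws are retained as the
  hypervolume's stochastic points (default 20 000 draws).

Box sampling was chosen over adaptive importance sampling because it is
simple, unbiased, and directly checkable against fine-grid integration of
the same KDE in low dimension — the package's tests do exactly that at a
10% tolerance.

The overlap of two hypervolumes is estimated on the union of their boxes;
the shared volume is clamped into `[0, min(V1, V2)]` before computing
unique fractions, since Monte-Carlo noise can otherwise produce a shared
volume marginally above a member volume. With
\(u_i = V_i - V_{shared}\) and \(V_{union} = V_1 + V_2 - V_{shared}\):

\[
\beta_{total} = \frac{u_1 + u_2}{V_{union}},\qquad
\beta_{shift} = \frac{2\min(u_1, u_2)}{V_{union}},\qquad
\beta_{rich} = \frac{|u_1 - u_2|}{V_{union}},
\]

so \(\beta_{total} = \beta_{shift} + \beta_{rich}\) holds as an algebraic
identity (2·min(a,b) + |a−b| = a+b), asserted on every comparison, and all
three lie in [0, 1] from complete overlap to complete separation.
Component shares are reported as percentages of the total.

**A caution on sampling noise.** Kernel-density regions estimated from
finite samples have noisy boundaries: the relative density error scales
like \((n h^d)^{-1/2}\), and in d = 4 at n ≈ 500 the boundary shell this
noise sweeps holds a substantial share of the region's volume. Two
samples from the *same* distribution therefore show a non-trivial
baseline β_total (of order 0.3 in four dimensions at that sample size,
smaller in lower dimension or at larger n). Interpret small-to-moderate
β values against this baseline rather than against zero; the package
deliberately does not inflate the bandwidth beyond Silverman's rule to
suppress it, because oversmoothing would also blur genuine niche
differences.

## The learner ensemble

Ten algorithms are available, with fixed, recorded hyperparameters — the
point of the ensemble is diversity of inductive bias, not per-learner
tuning:

| name | realisation | key settings |
|------|-------------|--------------|
| GLM | logistic regression, linear + quadratic terms | — |
| GAM | `mgcv` smooths per variable | k = 4, REML |
| MARS | logistic fit on fixed-knot hinge bases | knots at quartiles, ridge λ = 10⁻³ |
| CTA | `rpart` classification tree | cp = 0.01 |
| RF | `randomForest` | 300 trees |
| GBM | `xgboost` | 100 rounds, depth 3, η = 0.1 |
| ANN | `nnet`, standardized inputs | 5 hidden units, decay 0.01 |
| FDA | LDA on a quadratic basis expansion | — |
| MAXENT | L1-regularised logistic on linear + quadratic + hinge features | λ = 0.002 |
| SRE | bespoke percentile envelope on presences | q = 0.025 |

MARS and FDA are built from their defining constructions (hinge-basis
regression; discriminant analysis on an expanded basis) rather than a
dedicated package; MAXENT is realised as a regularised logistic model on
an expanded feature set, the standard equivalence. The SRE predicts 1 iff
every variable lies within the presences' [q, 1−q] percentile envelope —
a deliberately crude baseline that, as expected, tends to fail the
skill gates.

**Evaluation.** AUC is the rank (Mann–Whitney) statistic with midrank tie
correction, which equals trapezoidal ROC integration on tie-free data.
TSS(τ) = sensitivity + specificity − 1 is evaluated at every candidate
threshold — the sorted unique predictions and their midpoints, with
`prediction ≥ τ` counting as presence — and the maximum is reported with
its smallest argmax (a fixed tie rule).

**Cross-validation.** Each of 10 replicates draws a fresh stratified
5-fold partition (classes balanced across folds, appropriate for the
balanced design); every fold trains on 80% and scores on 20%, giving 50
runs per learner. A learner failing on a fold is recorded missing and
excluded from its own mean only. Gates are strict: mean TSS > 0.7 and
mean AUC > 0.8.

**Weights.** The default is equal weighting of the gated members (with a
`tss_proportional` option); the members are refit on the full table
before ensembling. Both conventions appear in practice, and the package
treats the choice as configuration, logging which was used. Ensemble
predictions are convex combinations of member predictions.

**Importance and curves.** Permutation importance of a variable is
1 − Pearson r between original predictions and predictions with that
variable permuted, averaged over 10 shuffles and clipped to [0, 1];
response curves sweep one variable across its observed range (100 grid
points) with the others at their medians.

## Projection, binarisation and change

The maxTSS threshold is computed once per model from its full-table
predictions and reused for all scenarios of that model — there is no
defensible way to re-threshold a future projection without future
observations. `≥ τ` counts as suitable (fixed tie rule). Change maps
classify each cell from its (current, future) binary pair into loss /
stable / gain / unsuitable, and two identities are asserted on every run:
loss + stable = current area and stable + gain = future area. Range
change is 100·(A_future − A_current)/A_current on cell-area-weighted km².
Population-level models are projected on the full grid but *reported*
within their own side of the boundary.

Two different "loss" numbers coexist by design: the range-change
percentage compares binary maps cell by cell, while the gap table's areas
are totals per scenario; both are reported rather than reconciled,
because they answer different questions.

## Gap analysis

MPA polygons are rasterized by the cell-centre rule — partial-cell
precision would be spurious at a 5′ working resolution. Percent protected
is 100·(protected km²)/(predicted km²), invariant to uniform rescaling of
cell areas. The loss class splits exactly into Priority Conservation
Areas (currently suitable, projected unsuitable, outside MPAs) and
Conservation Areas Pending Optimization (same trajectory, inside MPAs);
the two masks are disjoint and their union equals the loss class, also
asserted identities. When MPAs are placed independently of suitability,
percent protected approaches the MPA sea-coverage fraction — a null-model
check in the test suite.

## Reproducibility and problem sizes

A single base seed fans out to per-stage seeds via a stage-name hash, so
a stage's randomness does not depend on the order stages run; the run
manifest records the configuration and derived seeds needed to reproduce
a run byte-for-byte. The test suite exercises the full pipeline at a
15–30′ working resolution with 150–300 presences and 1–2 CV replicates;
the parameter-recovery check runs at the native 5′ resolution with 1000
presences and the full 5 × 10 cross-validation; the acceptance script
runs the complete pipeline at 15′ with 1000 presences. These sizes are
the package's choice of demonstration scale: they keep the full suite in
the minutes range while leaving every code path, including the native
resolution, covered.

## Known limitations

* Infinite dispersal is implicit: a cell that becomes climatically
  suitable is counted as range regardless of reachability.
* No extrapolation masking (MESS-style) is applied when projecting to
  scenario climates outside the training envelope.
* The pseudo-absence envelope rule is one reading of "conditions where
  the species does not occur"; inference is conditional on it.
* Hypervolume β values carry the finite-sample baseline discussed above.
* The synthetic generator's independence assumptions make the
  collinearity screen nearly vacuous on generated data (it matters for
  real predictor sets).
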
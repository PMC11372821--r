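# nichecast

Ensemble habitat-suitability modelling, niche-hypervolume comparison and
marine-protected-area (MPA) gap analysis for marine species with two
genetically distinct populations — built for conservation biogeographers
who want the whole chain, from occurrence records to "how much of the
projected range is protected?", as tested, reproducible R code.

The package grew out of analyses of the giant clam *Tridacna maxima* in
the Indo-Pacific (90–140° E, 11° S–15° N, 5 arc-minute grid), where an
Eastern Indian Ocean–South China Sea (EIOS) population and a Western
Pacific–Indonesia (WPI) population meet near the Makassar Strait. All
stages run end-to-end on synthetic data, so nothing has to be downloaded
to use, test or audit the methods.

## What it computes

**Occurrence prep.** Cleaning (duplicates, missing coordinates,
non-marine points), one-record-per-grid-cell thinning, population
assignment against a boundary polyline, and balanced pseudo-absences
drawn uniformly from sea cells outside the presences' environmental
envelope, giving a binary response *y* ∈ {0, 1}.

**Predictor screening and PCA.** Nine environmental layers (current
velocity, salinity, mean temperature, temperature range, depth, distance
to shore, dissolved oxygen, light at bottom, phytoplankton) are screened
iteratively so no retained pair has |Pearson *r*| ≥ 0.7 and no variable
has VIF = 1/(1 − R²) ≥ 10, then standardized and reduced by PCA.

**Niche hypervolumes.** Each population's realized niche is the region of
the first four PCA axes where a Gaussian product-kernel density (Silverman
bandwidth per axis) exceeds the 0.95 training-quantile threshold; volumes
come from uniform Monte-Carlo sampling of the bounding box. Pairwise niche
difference decomposes exactly as

  β_total = β_shift + β_rich,  β_total = (u₁ + u₂)/V_union,
  β_shift = 2·min(u₁, u₂)/V_union,  β_rich = |u₁ − u₂|/V_union,

with uᵢ = Vᵢ − V_shared: spatial replacement versus net
contraction/expansion, each expressible as a percentage share of the
total.

**Ensemble SDM.** Ten learners (GLM, GAM, MARS, CTA, RF, GBM, ANN, FDA,
MAXENT, SRE) are evaluated by 5-fold × 10-replicate stratified
cross-validation with the true skill statistic (TSS = sensitivity +
specificity − 1, maximized over thresholds) and rank-based AUC. Only
members with mean TSS > 0.7 **and** mean AUC > 0.8 enter the
equal-weighted ensemble; permutation importance (1 − *r* between original
and variable-permuted predictions) and evaluation-strip response curves
describe the fitted niche.

**Projection and change.** The ensemble is projected on current and
scenario stacks (2050s/2100s × RCP 2.6/RCP 8.5; only the four dynamic
layers change), binarized at the maxTSS threshold, and compared cell by
cell: loss / stable / gain / unsuitable, with range change
100·(A_future − A_current)/A_current on spherical cell areas (R = 6371 km).

**Gap analysis.** MPA polygons are rasterized by cell centre; the report
gives predicted km², protected km² and percent protected per scenario,
and splits the projected loss class into Priority Conservation Areas
(unprotected) and Conservation Areas Pending Optimization (inside MPAs).

Rasters are plain-text ESRI ASCII grids; occurrences are CSV; boundary
and MPAs are GeoJSON.

## Worked example

A complete synthetic analysis at demonstration scale (15′ grid, 300
presences, all ten learners, four climate scenarios):

```r
library(nichecast)
result <- run_demo(out_dir = file.path(tempdir(), "demo"), seed = 42)

print(result$niche$comparison)
#> niche_comparison: V1 = 92.65, V2 = 106.5, shared = 58.36
#>   beta_total = 0.585 = shift 0.487 + contraction/expansion 0.098
```

The two simulated populations differ in temperature and salinity optima,
and the hypervolume comparison finds a large total divergence (β_total
0.585 of a possible 1), mostly spatial replacement. Cross-validation
gates the learners:

```r
print(result$cv$species$summary, digits = 3)
#>    learner tss_mean  tss_se auc_mean  auc_se n_runs n_failed
#> 1      GLM    0.879 0.01013    0.971 0.00419     10        0
#> ...
#> 10     SRE    0.653 0.01541    0.827 0.00771     10        0
```

The surface range envelope misses the TSS gate (0.653 ≤ 0.7) and is
excluded; the remaining nine members form the ensemble. Warming shrinks
the projected range monotonically with scenario severity, and protection
of what remains stays near the simulated 16% MPA coverage:

```r
subset(result$range_table, level == "species")
#>     level     scenario range_change_pct
#> 1 species 2050s_RCP2.6           -4.684
#> 2 species 2100s_RCP2.6           -8.203
#> 3 species 2050s_RCP8.5          -15.078
#> 4 species 2100s_RCP8.5          -54.000

result$gap_report[c(1, 5), ]
#>       scenario predicted_area_km2 protected_area_km2 percent_protected
#> 1      current           11745433            1882289           16.0257
#> 5 2100s_RCP8.5            5402934             957468           17.7213

head(result$importance$species, 3)
#>           variable importance          se
#> 1 temperature_mean 0.54043697 0.013052394
#> 2         salinity 0.11161996 0.001381355
#> 3 dissolved_oxygen 0.07273585 0.002354127
```

Permutation importance correctly ranks mean temperature — the variable
that actually drives the simulated niche — first. The run directory holds
the full output contract: cleaned/thinned occurrence CSVs, the
collinearity report, the niche comparison, CV scores and exclusions per
level, response curves, continuous/binary/change rasters per level and
scenario, the range-change and gap tables, PCA/POCA masks, a manifest
and a per-stage log.

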
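---
title: "Methods: whole-slide amyloid-beta quantification in abquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-slide amyloid-beta quantification in abquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abquant)
```

# The problem and the pipeline

Amyloid-beta (Abeta) deposits — cored plaques, diffuse plaques, and
cerebral amyloid angiopathy (CAA) — are a neuropathological hallmark of
Alzheimer disease. On DAB-stained whole-slide images (WSIs) they can be
quantified automatically: a patch classifier `f(.)` scores every location
for the three deposit classes, a second classifier `g(.)` segments the
section into gray matter (GM), white matter (WM), and glass background,
and the two outputs are combined into per-region object counts and
densities per square micron that can be compared across a cohort.

`abquant` implements that workflow end to end:

1. **Preprocessing** — resolution harmonization to a single working
   resolution, Reinhard stain normalization against one reference
   profile, and uniform tiling with coordinate bookkeeping.
2. **Inference** — a sliding window evaluates `f` and `g` on
   fixed-size patches at a fixed stride, producing per-class confidence
   heatmaps and a region map on one shared grid.
3. **Quantification** — thresholding, small-component cleaning,
   connected-component ("blob") labeling, GM/WM attribution, the 1x6
   count vector, region areas, and densities.
4. **Visualization** — the standard overlay (cyan GM, yellow WM, orange
   deposits, black background).
5. **Cohort statistics** — median/IQR summaries, Kruskal-Wallis omnibus
   tests with Dunn-Bonferroni post-hoc comparisons, Wilcoxon rank-sum
   for two groups, chi-square/Fisher for categorical tables, and one-way
   ANOVA for demographics.

Because trained CNN weights are out of scope, classifiers are pluggable
behind a single contract ([patch_classifier()]); the package ships
deterministic *oracle* classifiers keyed to its own synthetic slide
generator, which makes the whole pipeline testable against exact ground
truth.

# Parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| `target_mpp` | 0.503 µm/px | working resolution (a 20x scan) |
| `tile_size_px` | 1536 | tile edge for preprocessing I/O |
| `patch_size_px` | 256 | classifier field of view |
| `stride_px` | 16 | sliding-window step; heatmaps are 1/16 resolution |
| `thresholds` | 0.9 per class | heatmap binarization cutoffs |
| `min_blob_cells` | 2 | cleaning floor for surviving components |
| `connectivity` | 8 | blob connectivity |
| `counting_mode` | `"blob"` | objects (default) vs `"patchvote"` cell votes |

The resolution, tile, patch, and stride values are the workflow's
published operating point. The per-class thresholds are not published;
0.9 is a deliberately strict default that, with one-hot oracle
classifiers, makes binarization exact. `min_blob_cells = 2` removes
single-cell specks, the smallest cleaning that still suppresses isolated
misclassifications.

# Geometry: what a heatmap cell means

Heatmap cell `(i, j)` (0-based) carries the classifier output for the
patch **centered** at slide pixel `(j*stride + stride/2,
i*stride + stride/2)`. Centering — rather than anchoring patches at the
cell's top-left corner — makes a cell's label describe its own location,
which in turn gives blob counting a clean semantics: a blob is the set
of cells whose representative pixels fall inside one deposit. Patches
overhanging the slide boundary are filled by symmetric reflection, so
the grid covers the entire slide (`ceil(H/stride) x ceil(W/stride)`
cells). The deposit heatmaps and the region map share this grid exactly.

Region labels are the argmax of `g`'s three probabilities, with exact
ties resolved by the fixed priority background > GM > WM.

Classifiers may expose an optional vectorized center-pixel fast path
(`pixel_fn`); the contract requires it to be exactly equivalent to full
patch evaluation, and the test suite verifies that equivalence for the
oracles against brute-force per-cell classification, across batch sizes,
and between both code paths.

# Stain normalization

Reinhard color transfer operates in the decorrelated log-opponent
(l-alpha-beta) space: RGB -> LMS cone responses -> log10 -> opponent
axes. Per channel the map is affine, `out = (in - mean_src)/sd_src *
sd_ref + mean_ref`, followed by the inverse transform and clipping to
0..255. Two practical choices:

* **Tissue-only profiling (default on).** Glass background dominates a
  WSI and would skew whole-image statistics, so pixels with mean RGB
  intensity >= 90% of the maximum are excluded from profile estimation.
  Both modes are available because the upstream workflow does not state
  which was used.
* **Tail sensitivity.** In log space the channel variance is dominated
  by the darkest pixels (dense plaque cores). Two sections with
  different deposit burdens can therefore have very different profiles,
  and transferring between them amplifies contrast until many pixels
  clip; the definitional guarantee — a normalized slide re-profiles to
  the reference within 1e-2 per channel — holds in the regime the
  method is designed for, namely correcting *batch effects* (the same
  tissue under a different scanner/stain color cast). The tests
  exercise exactly that scenario and also check that self-normalization
  is the identity within one gray level and that the map preserves
  within-channel rank order before clipping.

Resolution harmonization uses exact area-average resampling (sparse
row/column averaging operators), which preserves mean intensity to
within rounding; output dimensions are `round(n * mpp/target)` and the
output is declared to be at the target resolution. Only downsampling is
supported unless explicitly overridden, mirroring how mixed-resolution
scans are brought down to a common magnification.

# Counting

**Blob mode (default).** Each class's heatmap is binarized (values at or
above the threshold become one — "below the threshold" becomes zero, so
equality keeps the cell), components smaller than `min_blob_cells` are
removed, and maximal connected components under the chosen connectivity
are labeled in reading order by a two-pass union-find labeler (Rcpp).
Each blob is attributed by majority vote of its cells over the region
map: GM/WM ties go to GM, and a blob whose cells are majority background
is excluded (a detection on glass is not a plaque). The result is the
1x6 count vector ordered (GM-cored, GM-diffuse, GM-CAA, WM-cored,
WM-diffuse, WM-CAA). Counts are additive across disjoint slides, and
Table-style outputs report objects, which is why blob mode is the
default.

**Patch-vote mode.** The alternative accumulator increments a slot for
*every* tissue cell whose confidence exceeds its class threshold (class
= argmax, region = the cell's own label; background cells are skipped).
Votes are cells, not objects — totals are larger by roughly the mean
blob area — so outputs carry an explicit `mode = "patchvote"` tag. Both
modes are computed by [cmd_quantify()] because the published description
contains both a blob-labeling account and a one-hot accumulation
account, and the per-patch update of the latter is ambiguous; rather
than guess a single intent, both are implemented and labeled.

**Areas and densities.** A cell's physical footprint is
`(stride_px * mpp)^2` square microns, so 1000 GM cells at stride 16 and
0.503 µm/px cover 1000 x (16 x 0.503)^2 = 64,770.304 µm². Areas are
measured at heatmap resolution because that is the grid on which counts
are defined; density = count/area, reported missing when a region has
zero area and zero count, and an error when a count would be divided by
zero area.

# The synthetic slide generator

The generator emulates a DAB-stained temporal-lobe section at desk
scale: an elliptical tissue mask (semi-axes 0.46 of each dimension)
split into GM and WM either radially (outer GM band around a WM core,
mimicking the cortical ribbon; the default) or vertically, populated
with disjoint deposits:

* **cored plaque** — dense dark disc with a darker core (inner 35% of
  the radius);
* **diffuse plaque** — lower-contrast disc with a deterministic mottle
  texture;
* **CAA** — ring (outer 45% of the radius) around a pale lumen wash.
  The lumen carries its own palette color and decodes as CAA, so the
  oracle footprint is the full disc; this keeps the invariant that a
  patch centered on any placement returns confidence 1 for its class,
  which a bare annulus could not satisfy at its own center.

Every deposit signature has separate GM and WM color variants (13
palette entries in total) so that a single pixel determines both the
deposit class and the region it was rendered in. The minimum pairwise
distance between palette entries is ~49 RGB units; pixel noise is
achromatic Gaussian with sd 2.5 added to all three channels (a shared
luminance perturbation, which leaves the nearest-color decision
unchanged by construction and renders fast), so nearest-color decoding
has a >9-sigma margin and is error-free in practice. The oracle
classifiers are nothing more than that decoder applied to a patch's
center pixel; unknown colors decode to background/zeros.

Placement is rejection sampling under two constraints: the footprint
must lie strictly inside its intended region, and centers must be at
least `2 * (r_i + r_j)` apart, so footprints are pairwise disjoint with
a wide margin and the ground-truth object count is unambiguous. Default
radii are 28-44 px for plaques and 48-72 px for CAA: a disc of radius r
on a 16-px cell-center lattice always contains at least
`pi * (r - 8*sqrt(2))^2 / 256` centers, so r >= 28 guarantees >= 4
cells — comfortably above the 2-cell cleaning floor — and the
separation rule guarantees different deposits never share or abut cells.
This is what makes *exact* end-to-end count recovery a fair test rather
than a statistical one. The seed fully determines the raster; the
ground truth (placements, full-resolution region mask, expected 1x6
counts) is returned alongside and written into the slide's JSON sidecar.

What the generator does **not** emulate: nuclei and counterstain
texture, leptomeninges, anisotropic or overlapping deposits,
out-of-focus regions, scanner compression artifacts. Passing the
end-to-end tests therefore demonstrates that the pipeline machinery —
geometry, thresholding, labeling, attribution, arithmetic, statistics —
is exact, not that any particular CNN would reach this accuracy on real
tissue.

# The cohort simulator

Per case and per (class, region) slot, a density is drawn from a
log-normal distribution with the group's median (`meanlog =
log(median)`, so medians are preserved exactly) and common dispersion
`sdlog`, optionally zero-inflated; counts are Poisson with mean
`density * area`, and the reported density is `count/area` — what the
imaging pipeline would measure. Published tables give only medians and
interval summaries, so log-normality is a modeling choice, not a claim
of fidelity.

Defaults, calibrated once against the published per-group density
tables: GM area 2.6e8 µm² and WM area 8e7 µm² (back-computed from raw
counts vs densities in the densest severity group), and `sdlog = 0.6` —
an interquartile ratio near 2 implies `log(2)/1.35 ~ 0.5`, and reading
the two densest groups' median intervals as 95% CIs implies 0.59-0.69.
With n = 30 cases per group this dispersion separates a 1.5x median
ratio in rank order with high probability, which is what the
severity-gradient recovery check requires.

# Statistical battery

* **Summaries**: continuous pipeline outputs as median (IQR), quartiles
  by linear interpolation (R's type 7); demographics as mean (SD).
* **Kruskal-Wallis** via `stats::kruskal.test` (tie-corrected H,
  chi-square reference with k-1 df); an all-identical input returns
  H = 0, p = 1 rather than NaN.
* **Dunn's post-hoc** is implemented in-package (no suitable dependency
  is available): pairwise z on pooled mean ranks with the tie term
  `sum(t^3 - t)/(12(N-1))`, two-sided normal p, Bonferroni adjustment
  `min(1, p * k(k-1)/2)`. Post-hoc tests run only when the omnibus p is
  below 0.05, matching how such analyses are reported; the gate is
  configurable.
* **Wilcoxon rank-sum**: exact enumeration when the pooled sample has
  <= 12 observations without ties, otherwise the tie-corrected normal
  approximation without continuity correction; the path taken is
  recorded in the result.
* **Categorical tests**: `auto` picks Fisher when any expected cell is
  below 5, else chi-square without Yates continuity correction (the
  documented switch of R's 2x2 default). Zero-margin rows/columns are
  dropped with a notice. For larger-than-2x2 tables where the exact
  network algorithm fails, a seeded Monte-Carlo Fisher p is substituted
  and labeled as such.
* **One-way ANOVA** from explicit sums of squares so degenerate inputs
  are well-defined: identical groups give F = 0, p = 1; zero
  within-group variance with unequal means gives F = Inf, p = 0.
* **Missing data**: every analysis drops cases with a missing group
  label or outcome for that analysis only, with no imputation; group
  levels such as a deferred diagnosis can be excluded by name. No
  covariate adjustment is applied anywhere.

# Numerical choices and degenerate inputs

* Threshold boundary: `>=` maps to one (binarization keeps the cell at
  exactly the threshold).
* Blob label order: reading order of each component's first cell, so
  outputs are deterministic and reproducible across platforms.
* Region attribution ties go to GM; majority-background blobs are
  excluded from counts.
* Reflection indexing is symmetric (edge pixel repeated), applied to
  patch extraction, tile padding, and overhanging cell centers.
* `log10` of LMS values is guarded at 1e-4 to keep pure black finite.
* Config YAML and stain-profile JSON serialize named vectors as named
  mappings so round trips are lossless.

# Validation strategy and problem sizes

The test suite validates every stage against an independent oracle:
flood-fill labeling (exhaustively over all 65,536 4x4 masks and on 1000
random 64x64 masks, both connectivities), brute-force per-cell
classification for the sliding window (512x512 slides), closed-form rank
arithmetic and full-permutation enumeration for the statistics, and
hypergeometric tail sums for Fisher 2x2. End-to-end count recovery is
checked on 100 randomized slides of 2048-4096 px with 3-40 deposits each
and must be exact on all of them; calibration checks run the
Kruskal-Wallis test over 1000 null cohorts (type-I error within 3
Monte-Carlo standard errors of 0.05) and 200 shifted cohorts (power
above 95% for a 10x median shift at n = 30/group). These problem sizes
keep the full suite in the minutes range on a single CPU while leaving
the checks statistically meaningful; `scripts/acceptance.R` re-runs a
compact version of the same computations from scratch.

# Known limitations

* Oracle classifiers validate the pipeline, not biological
  classification accuracy; plugging in a trained CNN adapter via
  [register_classifier()] is the intended path to real data.
* Reinhard transfer between slides with very different deposit burdens
  amplifies contrast and clips (see above); on real cohorts the
  reference slide should be chosen to be representative, as the
  upstream workflow does by normalizing all slides against one
  reference.
* Areas and densities are measured at heatmap resolution; at stride 16
  the discretization error is at most one boundary row of cells.
* The cohort simulator models slots independently within a case; real
  per-case correlations between deposit classes are not emulated.
* Leptomeninges, capillary-vs-leptomeningeal CAA subtyping, and
  neuritic/compact plaque splits are out of scope.
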
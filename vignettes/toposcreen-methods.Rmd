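---
title: "Methods: simulating and analysing micro-topography differentiation screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing micro-topography differentiation screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The screening problem

A TopoChip is a 2 x 2 cm polystyrene chip carrying a 66 x 66 grid of
300 x 300 um wells ("TopoUnits"), each printed with one of 2175 distinct
micro-topographies plus a flat control, every design present in duplicate
with the duplicate displaced diagonally to rule out location bias.
Primary human keratinocytes seeded at low density on such a chip respond
to the surface structure: on some topographies an unusually large fraction
of cells undergoes terminal differentiation (scored by transglutaminase-1,
TGM1), and differentiated cells adopt either a round, confined morphology
or an unusually spread one. The analysis task is to (i) quantify per-cell
differentiation and shape from fluorescence images, (ii) rank units and
call hits robustly, and (iii) relate the hit classes back to quantitative
descriptors of the topographies with interpretable classification trees.

`toposcreen` implements that whole workflow, together with a synthetic
screen generator whose ground truth follows the same kind of
descriptor-driven decision structure, so every stage can be validated
against a known answer.

# Topography library and descriptors

Designs are random combinations of primitive shapes (circles, equilateral
triangles, rectangles). Per design the primitive count is uniform on 1-30;
sizes are log-uniform within 5-90 um per kind (so small and large features
are equally represented on a relative scale); positions are uniform within
the unit; rotations uniform on [0, 360). Rectangle widths derive from a
log-uniform aspect ratio in [1, 10]; rectangles with aspect ratio >= 3
count as "lines". These composition choices are the package's own: the
published libraries state only that primitives were combined at random.
With them, the library's coverage spans roughly 0-0.6 and the descriptor
thresholds used by the planted response model (below) all fall inside the
observed descriptor ranges, which is what makes the synthetic screen
informative.

Masks are rasterized at 0.5 um per pixel (600 x 600 per unit) with a
pixel-centre point-in-shape test, unioned over primitives and clipped at
the unit walls. The pixel-centre rule keeps masks strictly binary, which
the coverage descriptor requires. Rasterized coverage matches analytic
shape areas to within 1% for features of a few tens of micrometres; for
features around 10 um, coherent quantization along grid-aligned edges can
reach a few percent, which is why the geometry checks draw primitives in
the 30-80 um range. The smallest screen-relevant scale (circle diameter
around 8 um) is still resolved with more than 16 pixels across.

Descriptors per design:

* **FCP** - fraction of covered pixels.
* **FCPN01** - FCP under simulated experimental variation: the mean FCP of
  25 replicates in which every pixel flips independently with probability
  0.01. Because FCP depends only on the foreground count, the replicates
  are drawn as binomial flip counts, which is distributionally identical
  and has the closed-form expectation
  `fcp (1 - p) + (1 - fcp) p` used by the tests.
* **Wn bands** - share of non-DC spectral power in radial frequency
  annuli centred at 0.1, 0.2, 0.3, 0.5, 1, 2 and 4 cycles per 10 um, with
  edges at geometric midpoints; the top band extends to the spectral
  limit so the bands tile the whole AC spectrum and sum to exactly one.
  The spectrum is computed on a 2x block-averaged raster (1 um/px):
  its Nyquist limit, 5 cycles per 10 um, still sits above the highest
  band centre, at a quarter of the transform cost.
* **LineLen / CircDiam** - mean line length and mean circle diameter from
  the design metadata (the descriptors describe the design, not the
  image); absent when no qualifying primitive exists.
* **RotSD** - irregularity of primitive placement: rotations folded into
  each primitive's symmetry period (rectangle 180 degrees, triangle 120
  degrees), rescaled to a common [0, 180) range, summarised by the sample
  standard deviation. Circles are orientation-free and excluded; a single
  oriented primitive has zero spread.

# The synthetic screen and its planted response

The generator's defaults are the study conditions. Each unit receives a
uniform 5-25 cells, matching the density observed on screened chips.
A unit's differentiation probability and morphology class follow ordered
rules over its descriptors (first match wins; a condition on an absent
descriptor never holds, so the flat control is always baseline):

| rule | conditions | p(differentiate) | morphology |
|---|---|---|---|
| round, high coverage | FCP >= 0.256 and CircDiam >= 8.293 | 0.50 | round |
| spread, low coverage | FCP < 0.256 and LineLen < 15.849 and (FCPN01 < 0.397 or RotSD >= 40.876) | 0.45 | spread |
| round, low coverage | FCP < 0.256 and LineLen < 15.849 (otherwise) | 0.45 | round |
| baseline | none | 0.12 | round |

The rule thresholds are the descriptor split values reported for screened
chips; the rates 0.50/0.45 mirror the strongest observed responses
(50-60% positive cells) and the baseline the typical 10-15%, without
claiming to be estimates of them.

Per cell: spread area is log-normal (median 500 um^2 for round cells,
1800 um^2 for spread ones, sigma_log 0.5); roundness is beta-distributed
with mean 0.70 (round) or 0.30 (spread) at concentration 10; the
perimeter is derived as `P = sqrt(4 pi A / r)` so the circularity
statistic recovers the drawn roundness identically. TGM1 intensity is
Normal(600, 120) for differentiated cells and Normal(80, 40) truncated at
zero otherwise, so the positivity cutoff (median intensity > 270) sits
between the modes with misclassification below 0.5%. Undifferentiated
cells use the round morphology (confined stem cells).

The area sigma_log of 0.5 (per-cell CV about 53%) deserves a note: with a
visibly tighter value the per-unit mean spread areas of round units never
reach below `median - 0.5 SD` of the bimodal unit distribution, and the
"low" hit class that the downstream model needs would be structurally
empty. Screened spread-area distributions span roughly 200 to well over
1500 um^2 per unit, which this dispersion reproduces.

What the generator deliberately does not emulate: cell-cell adhesion and
density effects (differentiation is independent per cell, consistent with
the observed lack of correlation between positive and total counts),
proliferation or detachment between seeding and fixation (one static
snapshot), inhibitor perturbations, and any per-cell intensity structure
beyond the bimodal model - real immunofluorescence has spatially
correlated backgrounds, debris and unquantifiable units that the
simulation omits. Passing tests therefore validate the analysis code and
its statistical behaviour under the planted model, not the biology of any
particular chip.

# Image rendering and quantification

In image mode each cell is a rotated ellipse matching its drawn area and
roundness (axis ratio solved from the Ramanujan perimeter approximation).
Where bodies overlap, each foreground pixel belongs to the nearest
nucleus within its connected clump - the same partition the segmentation
stage computes, so noise-free rendering and quantification agree cell by
cell. DAPI shows 10 um nucleus disks, F-actin fills bodies at intensity
200, and TGM1 fills each cell at its own simulated intensity; Gaussian
noise is added per channel.

Quantification mirrors a standard high-content pipeline: Otsu threshold
on DAPI, 8-connected components, minimum nucleus area 30 um^2; cell
bodies by seeded propagation of the thresholded F-actin foreground (one
region per nucleus; a nucleus outside the foreground keeps a
nucleus-sized region); per-cell area from pixel counts; median TGM1
intensity per region; positivity strictly above 270 (the package
reconciles the printed "270" and "271" variants of that cutoff by using
a strict inequality at 270, configurable).

The perimeter estimator needs care: raw pixel-boundary lengths
overestimate smooth contours by up to 8%, which would visibly bias the
circularity statistic. The package traces each region's outer boundary,
smooths the closed chain with a five-sample circular moving average and
adds pi pixel units (the perimeter excess of a half-pixel offset of a
convex body) to correct the boundary-centre shrinkage. Rasterized disks
of radius 5-50 um then score circularity within 0.5% of 1, and squares of
cell-like size within about 2% of pi/4. The window of five samples is the
balance point: narrower windows leave staircase length on disks, wider
ones cut square corners. Holes in regions (which the generator never
produces) would be ignored by the outer trace.

# Hit selection and the classification model

Units are ranked per metric with thresholds recomputed from the data:
`median + k_top SD` and `median + k_bottom SD` over units with a defined
value (strict inequalities; units with no positive cell are excluded from
both the statistics and the calls). Defaults: spread area +2 / -0.5 SD,
roundness +2 / -1 SD, percent positive +2 / -2 SD. Duplicates join at the
design level by an either-qualifies rule; designs qualifying for both
classes are excluded with a warning.

The model stage trains on the spread-area hit classes by default (the
richest two-sided contrast in the synthetic screens). Descriptor absences
are imputed as 0 ("no such primitive"), logged; features with pairwise
r^2 > 0.75 are eliminated in canonical column order (FCPN01, essentially
a noisy copy of FCP, always falls here); the remainder is split 75/25
stratified by class.

Trees are grown by exhaustive Gini search over (feature, midpoint)
pairs - ties resolve to the earliest feature in column order, then the
smallest threshold, so the fit is exactly reproducible and matches a
brute-force oracle - to depth 5 with at least 8 rows per leaf, then
cost-complexity pruned. The pruning level is chosen by 10-fold
cross-validated misclassification with a conservative SE rule: the
simplest tree within `se_factor` standard errors of the minimum, default
2.5. The classic one-SE rule proved too permissive as a null guard: on
pure-noise labels (n = 200, 4 features) both this implementation and
`rpart` retain spurious splits in roughly half of datasets under one SE,
because chance patterns in a finite sample survive cross-validation
within that same sample; at 2.5 SE the trivial tree is returned about 95%
of the time while recovery of genuine planted structure is unaffected.
`se_factor = 1` restores the classic rule.

ROC curves and AUC use the mid-rank Mann-Whitney statistic, which equals
the trapezoidal area under the empirical ROC; a model "recovers" the
planted structure when its top-two-level features intersect the features
named by the planted rules.

# Problem sizes, determinism and numerics

The default full run uses the complete library (2175 designs plus the
flat control, 4352 occupied units, around 65 000 cells); descriptor
extraction for it takes on the order of a minute and a simulated screen
with model fit a few seconds, so the recovery evaluation repeats the
screen over 20 simulation seeds. Rendered-image quantification is
desk-scale per unit and is exercised on 50-unit fixtures; the pipeline's
image mode quantifies a 200-unit subsample by default.

Every stage takes an explicit seed (library, layout, simulation, split,
tree folds, descriptor noise), seeds are restored after use, and the run
manifest records MD5 hashes of all stage outputs; identical
configurations reproduce identical manifests. Descriptor tables are
cached with round-trip-exact numeric formatting so cached and in-memory
runs agree bit for bit. Degenerate inputs are handled explicitly: blank
images yield zero labels with a flag, constant masks have zero spectral
fractions with a flag, zero-variance metrics call no hits, single-class
training sets return a warned single leaf, and impurity ties in the tree
break deterministically.

# Known limitations

* Descriptors are computed from the in-silico designs, not from imaged
  chips; systematic fabrication artefacts are out of scope.
* The spectral band semantics (radial annuli in cycles per 10 um with
  geometric-midpoint edges) are one reasonable reading of "fraction of
  energy at wavenumber X"; other conventions would shift band values.
* The planted response is a first-match rule list over descriptors;
  real structure-phenotype relations are surely smoother and noisier.
* Hit thresholds are per-run realizations by design; printed cutoff
  values from any particular experiment are expectations to compare
  against, not constants of the method.
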
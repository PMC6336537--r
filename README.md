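# toposcreen

Micro-topography screening of keratinocyte differentiation: design,
simulate and analyse TopoChip-style screens in R.

A TopoChip is a polystyrene chip carrying a 66 × 66 grid of 300 × 300 µm
wells (TopoUnits), each printed with one of 2175 distinct
micro-topographies plus a flat control, every design duplicated with a
diagonal displacement. Primary human keratinocytes seeded on such chips
differentiate (scored by transglutaminase-1, TGM1, immunofluorescence) at
rates that depend strongly on the surface structure, and the
differentiated cells adopt either round or spread morphologies. This
package is for computational biologists and screening labs who want a
tested, reproducible implementation of the full analysis chain — and a
synthetic screen with known ground truth to validate it on.

The package covers:

* **Virtual library + chip layout** — random combinations of primitive
  shapes (circles, equilateral triangles, rectangles), rasterized to
  binary unit masks; duplicate placement on the chip grid.
* **Topography descriptors** — coverage `FCP`, noise-perturbed coverage
  `FCPN01`, radial spectral energy bands `Wn_x` (cycles per 10 µm), line
  length, circle diameter, and the placement-angle irregularity `RotSD`.
* **Synthetic screen** — a planted response model: ordered rules over
  descriptors assign each unit a differentiation probability and
  morphology class; cells are drawn per unit (5–25 cells, log-normal
  areas, beta roundness, bimodal TGM1 intensity) and optionally rendered
  as DAPI / F-actin / TGM1 image stacks with ground-truth labels.
* **Morphometry** — nucleus segmentation (Otsu + 8-connected
  components), seeded-propagation cell bodies, per-cell area, a
  smoothed-contour perimeter estimator so the circularity statistic
  `4πA/P²` scores a disk at ≈ 1, median TGM1 intensity, positivity at
  `MFI > 270`, and per-unit summaries (% TGM1⁺, average spread area and
  mean roundness of positive cells).
* **Hit selection** — per-metric thresholds recomputed from the data as
  `median ± k·SD` (spread area +2/−0.5, roundness +2/−1, %positive
  +2/−2), duplicate units joined per design by an either-qualifies rule.
* **Classification trees** — r² > 0.75 correlation filtering, stratified
  75/25 split, exhaustive Gini CART with cross-validated cost-complexity
  pruning, ROC/AUC by the mid-rank Mann–Whitney statistic, and a
  recovery report checking that the tree's top-two-level features
  intersect the planted rule features.

## Worked example

A full-scale screen: generate the library, compute descriptors, simulate
the screen under the default planted model, quantify, call hits and fit
the tree (descriptor extraction takes about a minute; everything is
seed-deterministic).

```r
library(toposcreen)

lib      <- generate_library(seed = 1)      # 2175 designs + flat control
layout   <- layout_chip(lib, seed = 1)      # 66 x 66, diagonal duplicates
features <- library_descriptors(lib)
model    <- default_planted_model()
screen   <- simulate_screen(lib, layout, model, features, seed = 3)
cells    <- classify_tgm1(screen$cells, cutoff = 270)
units    <- summarize_units(cells)
hits     <- select_hits(units, "avg_spread_area_pos")
fit      <- screen_model(units, features, model, default_config())
```

```
> layout
chip_layout: 66 x 66 grid, 2176 designs in duplicate (4352 occupied, 4 empty), offset (+33, +33)
> screen
screen_tables: 4352 units, 65025 cells, 20.9% planted above baseline
> round(count_correlation(units), 4)
[1] 0.1508
> hits
hit_table on 'avg_spread_area_pos': top > 1942, bottom < 263.5
  high 405, mid 3138, low 133, excluded 676
> fit$tree
topo_tree: 5 nodes (3 leaves), 319 training rows, alpha = 0
line_len < 15.87  (n=319)
  line_len < 2.509  (n=235)
    leaf: n=18 P(high)=0.000
    leaf: n=217 P(high)=1.000
  leaf: n=84 P(high)=0.048
> fit$recovery
recovery_report: recovered = TRUE, held-out AUC = 0.994
  top-level features: line_len
  planted features:   fcp, circ_diam, line_len, fcpn01, rot_sd
```

Reading the output: 4352 units were simulated; the number of TGM1⁺ cells
correlates only weakly with total cell count (r² = 0.15), as expected
when differentiation is driven by topography rather than density. Hit
thresholds are realizations of the `median ± k·SD` rule on this dataset
(here top > 1942 µm², bottom < 264 µm²). The fitted tree separates the
high-spread from the low-spread designs by line length with its root
split at 15.87 µm — next to the planted rule threshold of 15.849 µm —
and classifies held-out designs with AUC 0.99, so the screen's planted
structure is recovered (`recovered = TRUE`). The second split isolates
designs with no line primitives at all (absent line length is recorded
as 0 in the model's feature table).

An end-to-end run with cached stages, output files and a hashed manifest:

```r
run <- run_pipeline(default_config(out_dir = "run1", cache_dir = "cache"))
```

A thin shell front end for the same steps is installed at
`inst/cli/toposcreen` (`toposcreen design`, `features`, `simulate`,
`hits`, `model`, `run ...`).

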
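---
title: "Methods: pixel-graph polarization and colocalization analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pixel-graph polarization and colocalization analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pixelpol)
```

## The data model

DNA pixel-based surface proteomics reads out the spatial organization of a
cell's surface proteome without optics. Each antibody binding event carries a
unique molecular identifier (UMI) and is tagged, in two sequential reaction
rounds, with the identifiers of the two DNA "pixels" (UPI-A, UPI-B) whose
neighborhoods it fell into. A sequencing read is therefore an edge
`(upia, upib, umi, marker)` in a bipartite graph over pixel neighborhoods, and
a cell is a connected component of that graph. Partially overlapping pixel
neighborhoods make the component's internal structure informative: two
A-pixels that share a B-pixel neighbor captured antibodies from nearby patches
of membrane.

`pixelpol` implements the downstream analysis of such edge lists:

1. parse, UMI-deduplicate, and partition the bipartite graph into components
   (`parse_edge_list()`, `dedupe_events()`, `build_components()`);
2. call cells as components with strictly more than 7,000 edges
   (`call_cells()`), the conventional threshold for this assay;
3. derive a cells x markers count matrix and, per cell, an A-pixel x marker
   count table with a shared-B adjacency relation (`count_matrix()`,
   `pixel_table()`);
4. score per-marker *polarization* as Moran's I spatial autocorrelation on
   the pixel adjacency graph, standardized to a z-score
   (`polarization_scores()`);
5. score per-pair *colocalization* as the Pearson correlation of two markers'
   per-pixel counts, standardized against a pixel-permutation null
   (`colocalization_scores()`);
6. contrast conditions (acute vs. chronic stimulation) per marker and per
   pair with Mann-Whitney U tests (`differential_polarization()`,
   `differential_colocalization()`), and test dispersion changes with a
   Gini-coefficient permutation analysis (`variability_test()`);
7. interpret colocalization changes against immune-synapse zone assignments
   (`load_zone_map()`, `anchor_partners()`).

## Statistical models

### Polarization: Moran's I on the pixel graph

For one cell and one marker, let $x_i$ be the `log1p`-transformed event count
on A-pixel $i$, and $w_{ij} \in \{0,1\}$ the shared-B adjacency. Then

$$I = \frac{N}{W}\,
\frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j-\bar x)}{\sum_i (x_i-\bar x)^2},
\qquad W = \sum_{ij} w_{ij}.$$

Under random arrangement $E[I] = -1/(N-1)$. The default z-score uses the
closed-form randomization variance (which involves the sample kurtosis of
$x$); a permutation z (relabeling values across pixels) is available as a
cross-check and agrees with the analytic form well within Monte-Carlo error
on cells of realistic size. Weights are binary and row-unnormalized, and the
count transform is `log1p`; both are the simplest choices consistent with the
shared-neighborhood data model, and raw counts can be supplied through the
`transform` argument. Records are omitted (not zero-filled) when a marker's
counts are constant within a cell, where I is undefined.

### Colocalization: Pearson r with a pixel-permutation null

For a marker pair, r is the Pearson correlation of `log1p` counts across the
cell's A-pixels. The z-score standardizes the observed r against its null
distribution over `n_perm` shuffles of the second marker's counts across
pixels. Self-pairs and isotype-control antibodies are excluded; pairs where
either marker has fewer than `min_events = 5` events in a cell are skipped to
avoid degenerate correlations. In the batched table builder one row
permutation per iteration serves all pairs at once (each pair still sees
`n_perm` independent shuffles of its second marker; only the coupling across
pairs is shared, which leaves each pair's null marginal exact).

A note on baselines: per-pixel totals vary, and any common "pixel size"
factor induces positive correlation between all marker pairs. With the
default simulation geometry (below) this factor is Poisson-only and the null
z is centered; in data with strong capture-area variation the per-cell z
carries a positive baseline that cancels in acute-vs-chronic contrasts, which
is why all condition-level inference is based on contrasts rather than raw z.

### Condition contrasts

Per marker (or pair), the per-cell z-scores of the two conditions are
compared with a two-sided Mann-Whitney U test. Polarization and
colocalization contrasts use **Bonferroni** correction over tested items with
significance at adjusted p < 0.001; colocalization additionally gates on
$|\Delta \text{median } z| > 1$. We interpret the effect-size gate on the
median-z difference between conditions: the per-cell z is a distribution, so
a scalar gate must summarize it, and the median difference is the natural
companion of the rank test. Items with fewer than `min_cells` scored cells in
either condition are reported as untested and excluded from the Bonferroni
denominator. Differential *abundance* instead uses Benjamini-Hochberg with
adjusted p < 0.01 and log2 fold change > 1 — the asymmetry between the
abundance and spatial branches is intentional and mirrors common practice for
this assay's analysis stack.

### Variability: Gini permutation analysis

Cell-to-cell variability of polarization is measured by the population-form
Gini coefficient $G = \sum_{ij}|x_i-x_j| / (2n^2\bar x)$ computed on z-scores
shifted to nonnegativity by the pooled minimum (Gini requires nonnegative
input; the shift is shared by both groups so the difference is well defined).
The observed statistic $G_\text{chronic} - G_\text{acute}$ is contrasted
against 2,000 label permutations and against 2,000 Monte-Carlo resamples
drawing both groups with replacement from the pooled background; the reported
p is the maximum of the two add-one permutation p-values (a conservative
combination, since no combination rule is canonical), adjusted with
Benjamini-Hochberg at 0.01. The discreteness floor is
$p \ge 1/(n_\text{perm}+1)$.

### Abundance

Counts are normalized per cell with the centered log-ratio transform,
$\mathrm{clr}(c) = \log(c+1) - \overline{\log(c+1)}$, the convention for
antibody-count single-cell data (library size is technical). Clustering is
PCA (20 components) + k-nearest-neighbor graph + Louvain at resolution 1.
The log2 fold change backtransforms CLR values with `expm1` before averaging
groups; because CLR values can be negative, group means are floored at 1e-9
before the ratio — documented so the "greater than 1" cutoff is exactly
reproducible. Trogocytosis-confounded markers are flagged by labeling
clusters B-cell-like when mean CLR of a B-lineage anchor (default CD19)
exceeds the across-cluster mean by 1 CLR unit (a configurable margin; no
numeric rule is canonical) and running the B-vs-T differential contrast.
The CD4/CD8 phenotype helper labels a cell CD8-positive when CLR(CD8) >
CLR(CD4); this is an operationalization for subsetting, not a biological
claim.

## The synthetic-data generator

Every stage is testable without sequencing data through a generative model
with known ground truth (`simulation_config()`, `simulate_cell()`,
`simulate_experiment()`):

- A cell is a unit sphere with `n_a_pixels` and `n_b_pixels` pixels. The
  default layout is a **randomly rotated golden-angle (Fibonacci) spiral**.
  We deliberately do not place pixels uniformly at random by default: a
  random layout has a spatially autocorrelated capture-area field (sparse
  regions have large Voronoi cells whose neighbors are also large), which
  reads out as a positive Moran's-I baseline for *every* marker that grows
  with event depth (mean z per marker ≈ +4.6 at the default depth) and
  would make "kappa = 0" cells polarized by construction. The spiral layout
  equalizes capture areas, so unpolarized markers score near zero
  (mean z ≈ 0). `pixel_layout = "random"` restores fully random placement
  for studying that regime.
- Each of `n_events_per_cell` events draws a marker from condition-specific
  abundance weights, and a surface location from a mixture of the uniform
  sphere and a marker-specific von Mises-Fisher hotspot. The hotspot mixture
  weight is $\kappa/(\kappa+2)$, so $\kappa = 0$ is exactly uniform and
  increasing $\kappa$ monotonically increases both the fraction of events in
  the hotspot and its sharpness — one dial per marker and condition.
- Colocalization is induced by letting a pair share a hotspot center with
  probability `hotspot_sharing` (settable per condition, so a contrast can
  be injected in chronic only).
- Events attach to the nearest A-pixel and nearest B-pixel within
  `capture_radius` (great-circle angle, ties to the lowest pixel index);
  out-of-range events are dropped and accounted in the ground truth.
- UMIs are sequential integers per cell; duplicate reads repeat a record
  verbatim at `duplicate_read_rate` and collapse back under deduplication.
- Debris is added as small connected bipartite components (a zig-zag path
  plus random extra edges) below the calling threshold, to exercise cell
  calling.
- All randomness derives from `(seed, condition, cell index)` via a mixing
  function, so outputs are byte-reproducible and cells are independent.

**Default scales.** The study-like defaults are 300 A- and B-pixels,
12,000 events per cell, capture radius 0.3 rad, duplicate rate 0.1, and 50
cells per donor and condition with 10 debris components of 10-100 edges per
sample — deep enough that every true cell clears the >7,000-edge rule after
drop-out and deduplication (the per-cell edge-count distribution above the
threshold is not otherwise constrained). The packaged test-suite and
acceptance analyses use reduced cells (60 pixels, 400-500 events, capture
radius 0.45 — widened with sparser pixels so drop-out stays below ~10%) with
40 markers and 100 cells per condition, sizes at which the scorers retain
full power while a complete calibration run stays fast.

**What the generator does not emulate:** read-level sequencing error and
quality, pixel chemistry kinetics, UMI collisions, antibody aggregates,
trogocytosis transfer dynamics (trogocytosis enters only as planted
abundance structure), cell-size heterogeneity, and doublets other than
bridged components. Passing tests therefore demonstrate correctness of the
*statistics and their calibration on the stated generative model*, not
robustness to every artifact of real sequencing data.

## Numerical and design choices

- **Strict threshold.** Cell calling keeps components with edge count
  strictly greater than `min_edges` (default 7000); the boundary case is
  excluded by convention and covered by tests.
- **Component refinement.** Leiden modularity clustering (on the simple
  graph) is applied only to components exceeding a configurable size
  ceiling, off by default: the threshold rule operates on plain connected
  components, and refinement exists as the recovery path for merged cells.
- **Determinism.** Every stochastic stage takes a seed; child seeds are
  derived by integer mixing, never by sharing a global stream, so results
  are independent of evaluation order and parallelizable per cell.
- **Undefined scores** (constant values, edgeless graphs, zero null sd)
  signal as `NA`/omitted records rather than fabricated zeros, and
  downstream tests count only defined scores.
- **Canonical ordering.** Deduplication sorts records; pair tables are
  lexicographic with `marker_a < marker_b`; components sort by size. All
  outputs are therefore invariant to input order.
- **Bonferroni denominators** count tested items only. The spatial branch
  uses Bonferroni (strict familywise control over a structured panel), the
  abundance and variability branches Benjamini-Hochberg.
- Zone membership for the synapse report ships as an editable YAML config
  (anchors: CD3E for the cSMAC, CD11a for the pSMAC with CD54 and CD2, CD44
  for the dSMAC); all other markers are reported as "unknown" rather than
  guessed.

## Known limitations

- The analytic Moran variance needs at least 4 pixels and moderately sized
  graphs to be well calibrated; the permutation method is the fallback for
  tiny cells.
- The colocalization permutation null conditions on the observed marginal
  counts per marker but not on pixel totals; strong capture-area variation
  shifts all pairs' z jointly (see above). Condition contrasts are immune,
  but absolute z values should not be compared across datasets with
  different pixel geometry.
- Louvain clustering on a k-NN graph is deterministic given the seed but,
  like all modularity methods, resolution-dependent; the default
  (resolution 1, k = 15, 20 PCs) matches common practice for this data type.
- The Gini statistic is location-dependent through the pooled-minimum shift;
  alternative anchorings (e.g., shifting by a fixed quantile) would change
  absolute Gini values but not the permutation test's validity.

## Reproducing the calibration analyses

`scripts/acceptance.R --seed <int> --out <path>` re-runs, from scratch:
pair enumeration on the default panel, the full-scale cell-calling recovery
(3 donors x 2 conditions x 50 cells plus debris), dedup recovery against
ground truth, null calibration of all three differential tests (5
replicates), and effect recovery for polarization (kappa 4 to 8) and
colocalization (hotspot sharing 0 to 0.9) at 100 cells per condition,
writing each quantity to JSON. The test suite runs deeper versions of the
same checks (20 null replicates, 10 effect replicates) plus brute-force
oracle comparisons for Moran's I, Gini, and graph components.
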
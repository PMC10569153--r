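---
title: "Spatial immune contexture analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial immune contexture analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialmif)
library(dplyr)
```

spatialmif analyzes per-cell tables exported from multiplexed-immunofluorescence
(mIF) whole-slide images of tumor sections — cell centroids in micrometres plus
per-marker boolean calls or continuous intensities — together with a
tumor-boundary polygon. It reconstructs the standard immune-contexture readouts
for colorectal primary tumors and metastases: subset densities by
invasive-margin band, functional-marker fractions, direct-contact proximity
statistics, lymphoid-aggregate detection, cross-region correlations, and
GeoMx-style region-of-interest protein profiling. Because the imaging data such
analyses are built on are rarely shareable, the package also ships a
synthetic-tissue generator with known ground truth, and the whole pipeline is
validated against that truth.

## Phenotype gating

Cells are classified by hierarchical gating over marker calls. The default
configuration (`default_gating_config()`) encodes the four-panel colorectal
panel family — T cells (CD3/CD4/CD8/FOXP3 + PD-1 + CK20), myeloid cells
(CD68/CD163/CD66b + PD-L1 + CK20), B and gamma-delta T cells (CD20/TCRd), and
T-cell/APC interaction markers (HLA-DR/BCL6/TCF1) — and yields 14 immune
subsets: total CD4 and CD8 T cells; FOXP3+ Tregs; BCL6+ Tfh; HLA-DR+ activated
CD4 and CD8; TCF1+ CD4 and stem-like (TCF1+) CD8; B cells; gamma-delta T
cells; M1 (CD68+CD163-) and M2 (CD68+CD163+) macrophages; CD66b+ neutrophils;
and lineage-negative HLA-DR+ antigen-presenting cells.

Design points worth knowing:

* **Terminal labels vs membership.** Every cell gets exactly one terminal
  label (deterministic first-match, most specific gate first), but counting is
  by *membership*: a FOXP3+ CD4 T cell counts in both `treg` and `cd4_t`, so
  child counts can never exceed parents.
* **CK20 precedence.** A CK20+ cell is `tumor` regardless of immune markers;
  mIF spillover double-positives otherwise inflate immune counts. This is
  configurable (`tumor_precedence = FALSE`).
* **Lineage cocktail for APCs.** "Lin-" is operationalized as negative for
  CD3, CD20, CD68, CD66b and CK20 — the available lineage markers; the assay
  itself does not pin down a richer cocktail.
* **M1/M2 boundary.** CD68+CD163- is M1 and CD68+CD163+ is M2 by default;
  whether CD68-CD163+ singles should count as M2 is not determinable from the
  assay description, so it is exposed as `m2_requires_cd68`.
* **Ties at an intensity threshold are positive** (`threshold_markers()`), so
  continuous-input gating is reproducible.
* **Panels.** The four panels are stained on consecutive sections; real data
  should be gated per panel (`assign_phenotype(panel =)`). The synthetic
  pathway carries all markers on one table and gates them jointly.

## Compartmentalization by signed boundary distance

All regional analysis rests on the signed Euclidean distance d to the tumor
boundary (negative inside). Bands follow the conventional 0.5 / 2 / 5 mm
cutoffs: tumor core (d < -0.5 mm), inner invasive margin (-0.5 <= d < 0),
outer invasive margin (0 <= d < 0.5), juxtatumoral (0.5 <= d < 2), and distal
(d >= 5 mm). Intervals are half-open with d = 0 in the outer margin, so band
assignment is a total, deterministic function of d.

The 2–5 mm zone is genuinely ambiguous in the field's verbal definitions
("juxtatumoral to 2 mm; distal at 5 mm"): we label it `buffer`, exclude it
from five-band tables by default, and provide `merge_buffer = TRUE` to extend
distal down to 2 mm instead.

Distances are computed two ways: exactly, by point-to-segment distance against
the boundary polygon (default for tables up to ~50k cells), and on a raster
mask via Euclidean distance transform (10 um/pixel by default), which matches
whole-slide practice and provides band areas as pixel counts. The two agree
within one pixel diagonal (a tested invariant), and closed-form annulus areas
on a circular tumor are reproduced to well under 1% at 10 um resolution. With
multiple tumor islands, d is the distance to the nearest boundary and "inside
any island" counts as inside.

Within the tumor (core + inner margin), tissue is further split into cancer
island / stroma / necrosis. Necrosis requires declared polygons — the
morphology classifiers that recognize necrosis operate on image features the
cell table no longer has. Cancer islands are pixels whose local tumor-cell
count within a 50 um kernel reaches an occupancy threshold (default 20
cells/disc; both parameters exposed); everything else is stroma. Cells
inherit their pixel's class.

## Quantification

`density_table()` emits one row per sample x band x subset with count, band
area (mm^2), density, and log10(density + pseudocount). The pseudocount
(default 1 cell/mm^2) handles empty bands on the log scale; published figures
rarely state their zero handling, so the raw densities are always emitted
alongside. Fractions (`fraction_table()`) are percentages of nested
populations (Tregs within CD4; PD-1+ within a lymphocyte subset) and are
*missing*, never zero, when the denominator is empty.

## Proximity

The direct-contact statistic counts target cells within r = 10 um
(centre-to-centre, boundary inclusive) of each source cell — the radius at
which two cell centroids are close enough for membrane contact. Band
membership is taken from the indexed (source) cell, while neighbors may lie
in any band: a contact across the boundary is still a contact. Self-pairs are
always excluded when source and target populations overlap. Counting uses a
grid-bucket index (exact, near-linear); an all-pairs brute-force path is kept
and tested to agree exactly, and the acceptance suite re-checks it on random
instances. `contact_stats()` adds the contact fraction (% of source cells
with >= 1 target within r) and the mean nearest-neighbor distance.

## Lymphoid aggregates

Published pipelines typically detect lymphoid aggregates (LAs) with bespoke,
unpublished classifiers. This package uses density-based clustering (DBSCAN)
over T and B lymphocytes instead, because it is deterministic and
parameter-transparent: radius eps = 50 um and min_cells = 20 by default, a
cell counting itself toward its own neighborhood. Clusters below min_cells
are discarded; remaining lymphocytes are flagged sporadic. Aggregates closer
than eps merge — documented behavior, tested. Each aggregate carries its
convex hull, area, centroid, and composition (B, CD4, CD8, Tfh, BCL6+
counts).

Maturity follows the histological definition of a tertiary lymphoid
structure: germinal-centre evidence (>= 10 BCL6+ members) inside a B-cell
follicle (B fraction >= 0.3) classifies `mature_TLS`, otherwise `LA`. The
minimum sizes are declared defaults, not literature-derived constants — the
field has no agreed numeric criterion — and both are exposed in
`maturity_rules()`. Follicular-DC markers (CD11c) are not in the quantified
panels and play no role.

Summaries count aggregates by centroid band but split areas by geometric
intersection of the hull with the bands (rasterized at 5 um), since "number"
and "area share" are distinct quantities; the split areas sum to the hull
area within raster tolerance (tested).

## Association statistics

Cross-region Pearson correlations are computed per subset across samples
between band densities, on raw densities by default (log optional). Matrix
cells with n < 3 or a constant variable are missing with the reason recorded.
Paired primary–metastasis agreement is reported as R^2 over patient-matched
pairs. Group comparisons use two-sided Wilcoxon rank-sum tests — exact when
the combined n <= 20 without ties, normal approximation with tie correction
otherwise — with Benjamini–Hochberg adjustment within one band x subset
family of organ pairs (matching how per-panel significance is usually
displayed; a global family is configurable). Aggregate presence across organs
uses Pearson's chi-squared without continuity correction, warning when
expected counts drop below 5 rather than silently switching tests.

## GeoMx-style profiling

ROI x target protein counts are normalized by a single positive per-ROI
technical-control factor and rescaled to counts per 10^4 um^2 — the assay
literature names "technical controls and areas" without a formula, so the
package models the controls as one multiplicative nuisance per ROI. SNR is
the normalized count over the geometric mean of that ROI's isotype controls
(geometric, because isotype noise is multiplicative); zero isotypes are
floored with a warning. Targets whose mean SNR across ROIs is strictly below
2 are removed (2.0 exactly is retained); per-ROI masking is available because
published methods do not state whether filtering was global or per ROI.
Downstream comparisons report removed targets as `"filtered"`, never silently
absent.

## The synthetic-tissue generator

`simulate_tissue()` composes four stages, all driven by one integer seed
(child seeds are derived per stage, so regeneration is bit-identical):

1. **Geometry** — a star-shaped Fourier-perturbed boundary (always simple),
   optional circular necrosis pockets, and a square extent that must leave
   >= 5 mm of tissue outside the boundary so all five bands exist.
2. **Background cells** — an inhomogeneous Poisson process per subset whose
   intensity lambda(d) is a logistic transition between an intratumoral and a
   distal plateau plus a Gaussian bump at the invasive margin. Sampling is by
   thinning a homogeneous process at max lambda against a rasterized
   signed-distance field (10 um default), exact up to raster error — which is
   what makes Poisson-interval recovery a meaningful oracle.
3. **Aggregates** — a Thomas-style cluster process: centres drawn in bands
   from placement weights, members Gaussian-displaced (sigma = 40 um) with
   composition drawn from declared fractions; B-cell members acquire BCL6
   (germinal centre) with a per-archetype probability. Aggregate size is
   exactly `cells_per_aggregate` members. Truth polygons are recorded.
4. **Markers** — boolean calls implied by each truth label, plus PD-1/PD-L1
   flags, and optionally continuous intensities from per-marker
   positive/negative normal distributions so the gating path can be tested
   from raw intensities; misclassification under thresholding follows the
   analytic distribution overlap.

Four presets encode the organ archetypes as *rank orderings*, not calibrated
magnitudes — no quantitative per-organ density tables exist to fit against:

* `primary_like` / `lung_like`: infiltrated tumors (high intratumoral
  lymphocyte and APC density; intratumoral aggregates, which in primaries
  carry germinal centres and hence classify mature).
* `liver_like`: excluded phenotype — low intratumoral lymphocyte density with
  a strong outer-margin bump, M2-skewed macrophages, peritumoral aggregates
  without germinal centres.
* `peritoneal_like`: sparse infiltration throughout.

What the generator does **not** emulate: segmentation errors, staining
batch/slide effects, spatial marker-intensity gradients, nuclear morphology,
cell shapes and sizes (contacts are centroid-based), anisotropy, tissue folds
and holes. Passing recovery tests therefore demonstrates that the analysis
stages are correct *given* a faithful cell table, not that upstream imaging
error is survivable.

## Numerical choices and problem sizes

* Raster resolution 10 um/pixel default; cohort simulations in the test and
  acceptance suites use 20 um with a 1.2 mm tumor radius in a 13.2 mm extent
  (about 50–70k cells per sample), which keeps a 2 x 20-sample cohort
  comparison at roughly 45 s while leaving band areas within a fraction of a
  percent of closed form.
* The Poisson density-recovery check runs 20 replicates of a constant
  intensity (100 cells/mm^2) and requires each band x replicate count to fall
  in its central 99% Poisson interval; with ~120 such checks a handful of
  misses is expected by construction, so up to 5 are tolerated — the
  corresponding binomial tail probability is below 1e-3.
* All-null false-discovery control is checked by simulation (1000 repetitions
  of 20 independent rank tests) at q* = 0.1 within three Monte-Carlo standard
  errors.
* DBSCAN border points join the cluster of their *nearest* core neighbor
  (ties to the lowest cluster id) and cluster ids are renumbered by smallest
  member index, making the clustering order-independent and deterministic.
* Degenerate hulls (collinear members) are theoretically possible but not
  guarded beyond the min_cells >= 3 precondition.

## Worked example

```{r example, eval = FALSE}
tis <- simulate_tissue("liver_like", seed = 1, resolution = 20,
                       extent_um = 13200, tumor_radius_um = 1200)
res <- analyze_sample(tis$cells, tis$geometry, run_config(resolution = 20),
                      field = tis$field)
res$metrics
autoplot(res$las)
plot_density(res$density, subsets = c("cd8_t", "b_cell", "apc"))

sig <- cohort_signature(seed = 1, n_per_arm = 20)
sig
```

`cohort_signature()` is the end-to-end check: two simulated cohorts
(lung-like vs liver-like, 20 samples each) compared on core lymphocyte
density, core APC-to-T-cell availability, and intratumoral aggregate count,
BH-adjusted as a family of three.

## Known limitations

* Necrosis must be supplied as polygons; there is no image-based necrosis
  detection.
* Proximity is centroid-based; no cell-shape contact model.
* The GeoMx normalization models technical controls as a single scale factor;
  instrument-specific control structure is out of scope.
* Archetype presets are qualitative. Conclusions about magnitudes in real
  cohorts require real calibration data.
* Panels gated jointly (the synthetic path) assume co-registered markers; on
  real consecutive sections, gate per panel.
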
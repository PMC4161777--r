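---
title: "Phenotyping circulating tumour cells by ALDH1 level and TWIST localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping circulating tumour cells by ALDH1 level and TWIST localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctcpheno)
library(dplyr)
```

## The measurement problem

Circulating tumour cells (CTCs) are epithelial cells found at extreme
rarity in peripheral blood — on the order of one per hundred thousand to
one per million peripheral-blood mononuclear cells (PBMCs) on a cytospin
slide. Detecting them by immunofluorescence and then *phenotyping* each
one individually poses three coupled problems:

1. **Detection.** A CTC is called from a cytokeratin (CK) stain plus
   cytomorphology: the cell must be CK-positive, larger than the white
   blood cells around it, and have a high nuclear-to-cytoplasmic (N:C)
   area ratio. A CD45 double stain can additionally exclude leukocytes
   with ectopic CK expression.
2. **Stemness grading.** ALDH1, a putative cancer-stem-cell marker, is not
   simply present or absent: its level matters. The imaging platform
   expresses level as the *exposure time* needed to detect the signal —
   a dimmer cell needs a longer exposure, so lower values mean stronger
   expression — and the high/low/negative cut-offs are calibrated on
   labelled control cells.
3. **EMT state.** TWIST, an epithelial–mesenchymal-transition
   transcription factor, acts in the nucleus; its subcellular localization
   (nuclear vs exclusively cytoplasmic vs absent) is the readout, not its
   amount.

Each CTC then carries one of four co-expression phenotypes —
ALDH1^high^/TWIST^nuc^, ALDH1^high^/TWIST^cyt/neg^,
ALDH1^low/neg^/TWIST^nuc^, ALDH1^low/neg^/TWIST^cyt/neg^ — and phenotype
frequencies are aggregated per patient and compared across cohorts
(early vs metastatic disease).

This vignette documents the models, parameter choices and numerical
conventions behind each stage, and what the synthetic-data generator does
and does not emulate.

## The ALDH1 exposure-equivalent calibration

The platform readout is an exposure value on a regular grid (multiples of
5 units). The package models the intensity-to-exposure transform as

$$E(I) = \mathrm{clip}_{[E_{\min}, E_{\max}]}\Big(5 \cdot
\mathrm{round}\big(\tfrac{c}{5\,(I + \varepsilon)}\big)\Big),$$

a strictly decreasing reciprocal map quantized to the grid. The true
platform transform is proprietary and undocumented; any monotone
decreasing map reproducing the calibration grid is equally valid for
classification, and the reciprocal form was chosen because it is
invertible — `exposure_to_intensity()` lets the simulator render a cell
whose measured intensity lands exactly on a target exposure value, which
makes the calibration round-trippable and testable. The constant $c$
(default 4.5) anchors the high-class median exposure (15) to a bright
reference intensity of 0.3 on the 0–1 intensity scale; $\varepsilon$
(1e-6) only guards the origin.

Class cut-offs are *derived from labelled control cells*, not fixed:
`derive_cutoffs()` takes per-class exposure measurements (the package
default emulates 500 cells per class, the size of the control panel that
defined the published cut-offs), records each class's range, median and
standard error, and adopts the observed class boundaries:

```{r calibration}
ctrl <- simulate_control_cells(n_per_class = 500, seed = 7)
cal <- derive_cutoffs(ctrl)
cal
```

With the default control population this reproduces the canonical grid —
high ≤ 25, low 30–55, negative ≥ 60, class medians 15/45/70 — and
`classify_aldh1()` is then a total, deterministic step function on the
grid. Values in the inter-class gaps (26–29, 56–59) are unreachable after
quantization; encountering one signals a mis-calibrated model and raises
an error rather than a silent guess.

`simulate_control_cells()` builds each class as a balanced multiset:
class extremes always present, remaining values paired symmetrically
about the class median. This deliberately emulates the *location* of the
labelled control population — the class median is exact for any seed,
while individual draws vary. A plain uniform draw over the class range
would not have this property (the centre of the 30–55 grid is 42.5, not
the observed 45).

## Segmentation and morphology

Nuclei are segmented from DAPI with an Otsu threshold (configurable
offset), hole filling, and a marker-based watershed on the distance
transform (`tolerance = 1`) to split touching nuclei; objects below
`min_area` (default 20 px², about half a PBMC nucleus) are discarded.
Cell masks grow from each nucleus over the CK-positive region connected
to it, bounded by `dilation_limit` (default 8 px) and assigned to the
nearest nucleus where cells compete; CK-negative cells (PBMCs) receive a
thin default rim (`base_radius` = 1 px) so that every cell has a defined,
possibly empty, cytoplasm compartment. CK positivity itself is called at
mean + 5 sd of the non-nucleus background, which is robust to global
intensity shifts because CK-positive cells are rare by assumption.

Conventions, stated once and used everywhere: 1-based (row, col)
indexing; masks are integer label images with 0 background; nucleus and
cell masks of one cell share a label; cells clipped by the image border
are kept and flagged (`on_border`) rather than dropped — CTCs are too
rare to discard.

Morphology per cell: areas, equivalent diameter
$d = 2\sqrt{A_{cell}/\pi}$, and N:C ratio $A_{nuc}/A_{cell} \in (0, 1]$.
Per channel, mean and total intensity are reported over nucleus,
cytoplasm and whole cell. ALDH1 classification uses an *interior* cell
mean (mask eroded by 2 px): edge pixels cover the cell boundary only
partially and dilute the mean downwards, which near a class boundary
would bias the exposure-equivalent upwards by a full grid step. The
erosion falls back to the whole-cell mean for cells too small to erode.
ALDH1 is measured over the whole cell (nucleus + cytoplasm) because the
assay reports a single per-cell level with no compartment distinction.

## CTC criteria

The qualitative criteria — "larger than white blood cells", "high N:C
ratio" — need numbers to be computable. Both are exposed in
`ctc_criteria()` with documented defaults:

* **Size**: equivalent diameter ≥ `size_margin` (1.25) × the per-image
  WBC reference, itself the median equivalent diameter of CK-negative
  cells (≥ 20 required, else a configured fallback constant must be
  supplied). The margin tolerates the spread of PBMC sizes while a
  typical tumour cell (≈ 18 µm vs ≈ 8 µm PBMC nuclei) clears it easily.
* **N:C ratio**: ≥ `nc_ratio_min` (0.5). Carcinoma cells on cytospins
  have nuclei filling most of the cell; PBMCs pass this criterion too
  (they are nearly all nucleus) — the discriminating criteria for them
  are CK and size, and the N:C criterion instead guards against
  CK-positive debris and doublets.
* **CD45 mode** is a separate quality-control path for the double-stain
  panel (DAPI/CK/CD45), not a fourth channel of the triple stain,
  mirroring the two staining panels of the assay.

Every failed criterion is recorded per cell (`fail_reasons`), so
specificity failures are attributable.

## TWIST localization

A compartment is TWIST-positive when ≥ `min_positive_fraction` (0.3) of
its pixels exceed the detection threshold (background mean + 5 sd by
default). The localization rule is asymmetric by design: **nuclear
detection dominates** — a cell with both nuclear and cytoplasmic signal
is `nuc`, because nuclear presence is what licenses transcriptional
activity; only exclusively cytoplasmic signal scores `cyt`. An empty
cytoplasm mask scores cytoplasm-negative rather than erroring.

## Phenotypes, patients, cohorts

`assign_phenotype()` collapses the marker calls exactly as the reporting
taxonomy does: ALDH1 low and negative merge to `lowneg`, TWIST
cytoplasmic and negative merge to `cytneg`. Patient summaries express
each phenotype as a percentage of that patient's CTCs; cohort summaries
report, per category: patients with *any* CTC of the category, patients
*exclusively* of it (all their CTCs share it), the unweighted mean of
per-patient percentages, and the category's share of the pooled CTCs.
Detection rates are computed over all patients; every other statistic
covers detected patients only, following the convention of the source
tables.

Percentages are rounded to one decimal **only at reporting time**, with
half-up rounding (13/80 → 16.3%), matching clinical-table practice;
internal arithmetic is unrounded so rounding error never accumulates.

Cohort contrasts use the chi-square test with continuity correction
(Yates) on 2×2 patient-frequency tables, the Mann-Whitney test on
per-patient percentage distributions (exact for small untied samples,
tie-corrected normal approximation otherwise — the method used is
recorded in the output), and Spearman's rank correlation on pooled
per-CTC binary indicators within a cohort. The pooling choice for the
correlation is an assumption: the source describes the correlation "on
CTCs" of a cohort without specifying the unit, and pooling single CTCs
across patients is the reading adopted here. Whether CTC-negative
patients enter the Mann-Whitney samples as zeros is likewise unstated at
the source; detected-only is the default, switchable via
`include_negative`. No multiple-testing correction is applied by
default, mirroring the source analysis; `bh = TRUE` appends
Benjamini-Hochberg adjusted p-values.

```{r compare}
early <- simulate_cohort("early", n_patients = 80, seed = 1)
met <- simulate_cohort("metastatic", n_patients = 50, seed = 2)
cmp <- compare_cohorts(early, met)
glance(cmp)
```

## The synthetic cytospin generator

`simulate_cytospin()` emulates what the pipeline needs to be testable,
not optics:

* Cells are flat-top, hard-edged discs (pixel-centre sampling): a disc
  nucleus plus an annular cytoplasm. Hard edges make the rendered
  geometry an exact ground truth, so measured areas and N:C ratios can
  be validated against analytic disc geometry; soft (Gaussian-shoulder)
  edges would dilute edge means and bias the exposure round-trip.
* PBMC nuclei average 8 px, tumour cells 18 px at a nominal 1 px = 1 µm —
  preserving the "larger than white blood cells" ordering without
  claiming real magnification. Tumour N:C defaults to 0.8.
* PBMCs are CK-negative but carry non-zero uniform ALDH1/TWIST
  background (0.02–0.06), as real PBMCs show detectable background
  expression of both markers.
* Tumour ALDH1 intensity is `exposure_to_intensity()` of a true exposure
  drawn from the target class's grid span, so the calibration transform
  recovers the class by construction; TWIST is rendered in nucleus
  and/or cytoplasm per the ground-truth localization (nuclear cells
  co-express cytoplasmic TWIST half the time, exercising the
  nuclear-dominance rule).
* Additive Gaussian noise (sd 0.02 on the 0–1 scale), then clipping.
* A slide carries hundreds of PBMCs per field rather than a quarter
  million: patient-scale analysis is represented as many fields, keeping
  single images at desk scale. Placement is rejection sampling with a
  hard non-overlap constraint; exceeding the packing limit is an error,
  not a silent overlap.
* Reproducibility: every cell draws its attributes from its own derived
  RNG stream, a pure function of (seed, cell kind, index), so adding or
  removing a spiked cell never reshuffles the attributes of other cells;
  placement can relocate only the few neighbours that competed for the
  vacated space. The same seed and configuration give bit-identical
  images.

What the generator does **not** emulate — and therefore what passing
tests do *not* show about real data: point-spread functions, chromatic
aberration and channel bleed-through; focus variation and 3-D structure;
autofluorescence textures; cell clusters and apoptotic fragments;
staining-batch variation; and wet-lab losses. The published spike-in
*recovery rates* depend on those losses, so the package models recovery
abstractly (`simulate_spike_in()`): each spiked cell survives each
processing stage independently, making expected recovery the product of
stage retentions — a property testable by closed form, while the
published percentages themselves are hardware- and biology-dependent and
out of reach of simulation.

`simulate_cohort()` generates the tabular cohort structure directly:
Bernoulli detection, a zero-truncated negative-binomial CTC burden per
detected patient, and a multinomial phenotype split. Its defaults mirror
the observed cohort structure (early: 16.3% detection, pools dominated
by ALDH1^low/neg^/TWIST^cyt/neg^; metastatic: 50% detection, larger
burdens, ALDH1^high^/TWIST^nuc^ dominant).

## Numerical choices and degenerate inputs

* Exposure grid step 5 is a model invariant (every calibrated value is a
  multiple of 5); off-grid inputs error.
* Watershed tolerance 1 on the distance transform: deep enough to ignore
  noise dimples, shallow enough to split doublets with distinct centres.
* Blank DAPI channel → empty segmentation (not an error); zero-size
  image, overlapping forced spike positions, overcrowded lawns → errors.
* A patient with zero CTCs is CTC-negative: patient-level phenotype
  summaries refuse it, cohort summaries count it only in the detection
  rate.
* Constant vectors leave Spearman's rho undefined; flagged, not errored.
* Test and validation problem sizes — fields of 192–288 px with 80–150
  PBMCs, a handful of spiked cells per field, 50 fields for specificity,
  cohorts of thousands of patients for parameter recovery — were chosen
  so the whole suite exercises every stage at desk scale.

## Known limitations

* The intensity→exposure transform is a modelling convention; only its
  monotonicity and grid are anchored by the calibration data.
* Physical scales (pixel size, intensity units) are conventions; the
  source reports no pixel sizes or intensity units.
* Segmentation is tuned for cytospins (well-separated round cells) and
  will undersplit dense clumps beyond watershed reach.
* Cluster/microemboli handling and apoptotic-cell exclusion are out of
  scope, as in the source assay description.
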
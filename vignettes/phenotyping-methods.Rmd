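---
title: "Phenotyping colonic plasma cells from spatial single-cell proteomics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping colonic plasma cells from spatial single-cell proteomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sscpgate)
```

## The analysis problem

Spatial single-cell proteomics (SSCP) instruments image multiplexed antibody
panels on tissue sections and export, after vendor-side segmentation, a table
of per-cell raw fluorescence intensities with centroid coordinates. This
package implements the downstream analysis for colonic mucosa: quantifying
the B-lineage compartment of the lamina propria (LP) and, in particular, the
maturation state of CD138^+^ plasma cells (PCs). Intestinal PCs mature
through three stages distinguishable by two surface markers: early
CD19^+^CD45^+^, intermediate CD19^-^CD45^+^, and terminally mature
CD19^-^CD45^-^ cells. Shifts among these stages change the gut's capacity to
secrete dimeric IgA, so their per-patient fractions are the scientific
readout the pipeline is built around.

The stages are:

1. **Isotype background subtraction.** Each target antibody has a host
   isotype class (mouse IgG1 or rabbit IgG), and the panel carries one
   non-binding control channel per class. For every cell, the control
   intensity of the matching host is subtracted from each target and
   negative values are clamped to zero. Corrected intensities feed the
   continuous summaries (per-subtype median levels).
2. **Positivity calling.** A cell is positive for a target when its
   intensity reaches the host-specific cut-off: 30 fluorescence units for
   mouse IgG1-hosted targets, 100 for rabbit IgG-hosted ones. The boundary
   is inclusive.
3. **Follicle exclusion.** Fields of view (FOVs, 0.5 × 0.5 mm) containing
   part of a lymphoid follicle or aggregate are removed, because organized
   B-cell structures would otherwise dominate LP immune-cell fractions.
4. **Hierarchical gating.** Vimentin^+^ cells are LP-resident; among them,
   CD138^+^ cells are PCs (subtyped by CD19/CD45 signs) and
   CD19^+^CD27^+^CD38^+^CD20^-^CD138^-^ cells are plasmablasts (PBs).
5. **Summaries and statistics.** Per-patient marker-positive fractions of
   Vim^+^ cells, PC-subtype fractions, relative abundances (control median
   scaled to 1), per-subtype marker summaries, nearest-epithelium distances,
   Vim^+^ density per mm², and two-sided Mann–Whitney comparisons with
   optional Holm–Šídák adjustment.

## Design choices where the procedure was genuinely open

**Positivity basis.** The preprocessing description fixes cut-offs and
describes background subtraction, but does not pin down whether the 30/100
thresholds apply before or after subtraction. The package defaults to
calling positivity on **raw** intensities — the cut-offs were calibrated
against the isotype controls themselves, so applying them after the controls
have been subtracted would double-count the background — and keeps the
choice configurable (`basis = "corrected"` in `call_positivity()`).
Subtraction then feeds only continuous-level summaries.

**Scope of the follicle filter.** Follicle exclusion is stated for analyses
of *total* immune cells; whether PC-subtype analyses also excluded those
FOVs is not stated. The package applies the filter to **all** stages by
default (`follicle_filter` in the pipeline config), on the argument that a
follicle's B-cell mass distorts any denominator; the single exception is
that epithelial cells from flagged FOVs still serve as distance anchors,
because they define tissue geometry rather than an immune denominator.

**"other" PCs.** Published subtype figures show a fourth, unnamed "other"
slice. The three named subtypes leave exactly one CD19/CD45 combination
unaccounted for, so `other` = CD19^+^CD45^-^.

**PB gate and Vimentin.** The plasmablast marker string omits Vimentin, but
every reported immune fraction is computed within Vim^+^ LP cells, so the PB
gate requires Vim^+^ as well.

**Distance frame.** Nearest-epithelium distances default to the stitched
per-patient coordinate frame (tissue is contiguous across FOV boundaries);
`within_fov = TRUE` restricts the search to each cell's own tile. Ties among
equidistant anchors are irrelevant because only the distance is consumed.
The accelerated k-d tree backend is required by the test suite to agree with
an exhaustive scan.

**Quartile convention.** Medians and IQRs use linear interpolation between
order statistics (type 7); other conventions are available through the
`type` argument and never change any gating decision.

**Multiple comparisons.** Where several markers are compared at once the
report always carries both the unadjusted per-comparison p values and the
Holm–Šídák step-down adjustment, rather than guessing which convention a
reader wants. Automated outlier pruning (e.g. ROUT) is deliberately not
implemented; reports reflect all retained cells.

## The synthetic-tissue generator

Real cohorts cannot ship with the package, so `synthetic_spec()` /
`generate_cohort()` produce seeded cohorts with ground truth
(`truth.csv`) that emulate the *statistical* structure the analysis
assumes. The geometry is deliberately simple: FOVs are laid in a single row
so the epithelial band (the top `epithelial_band_frac` of every FOV) is one
contiguous strip with the LP below it — mimicking a mucosal biopsy section
and keeping "distance to epithelium" monotone in LP depth.

Defaults, chosen once:

* **6 + 6 patients, 8 FOVs × 400 cells** — a realistic two-group SSCP
  cohort; recovery tests that need ~2,000 PCs per patient raise
  `cells_per_fov` to 2,800 instead of changing any fraction.
* **25% epithelial cells, 12% PCs among Vim^+^ LP cells** — matches a
  typical export in which roughly one in eight analysed LP cells is a PC
  (reported cohorts run at a median of ~1,900 PCs among ~16,000 cells per
  patient).
* **Planted subtype fractions** 44.6/25.0/15.5/14.9% (case) versus
  13.2/30.0/32.7/24.1% (control) — an early-shifted disease group against a
  maturation-dominated control group, echoing published per-group medians.
* **Lognormal intensities** (multiplicative noise is the norm for
  immunofluorescence): positive signal `meanlog = log 400, sdlog = 0.5`,
  negative signal `log 3, 0.7`, isotype background `log 5, 0.5`, additive
  background coupling 1. On this scale both cut-offs (30/100) sit many
  standard deviations below positive signal and above negative-plus-
  background, giving per-marker call error rates of a few per mille —
  non-zero, as in real data. The control channels carry the pure background
  draw, so subtraction cancels the coupled background exactly when
  `coupling = 1`.
* **Graded PC marker programmes:** Ki-67 positivity falls from 30% (early)
  to 3% (terminal); CD38, CD138, NF-κB p65 and pan-RAS levels step down
  along maturation, so per-subtype summaries have a planted rank order.
* **Distance bias:** the terminal CD19^-^CD45^-^ subtype draws its LP depth
  from Beta(1, 3) instead of uniform, planting the observed
  closer-to-epithelium ordering.
* **Follicle FOVs** (12.5% of FOVs, i.e. one in eight) receive a dense disc
  of 200 extra B cells and the `contains_follicle` flag — enough structure
  to exercise the filter without simulating germinal-centre biology.
* The `preset = "separation"` intensity model (signal at `log 5000`, zero
  negative signal and background) creates perfectly separable cells; under
  it the pipeline must reproduce every truth label exactly, which the test
  suite asserts as a diagonal confusion matrix.

Per-patient seeds derive from the master seed as
`(master × 1000 + patient_index) mod (2³¹ − 1)`, so any patient can be
regenerated alone.

What the generator does **not** emulate: segmentation errors and doublets,
spatial autocorrelation of marker expression, cell-shape/area dependence on
crowding, batch effects between runs, and biologically structured follicles.
Passing tests therefore demonstrate correctness of the analysis logic under
the stated statistical assumptions, not robustness to those artefacts.

## Numerical and degenerate-input conventions

* FOV squares are half-open `[origin, origin + side)`, so a boundary cell
  belongs to exactly one FOV; centroids up to 1 µm outside their declared
  square are accepted with a warning (segmentation centroids can straddle
  tiles), farther is an error.
* Tables are written with 17 significant digits so numeric round-trips are
  bit-identical.
* A patient with zero Vim^+^ cells (or zero PCs) yields missing fractions
  with a warning — never silent zeros. An empty gate is vacuously true and
  warned about. Exact Mann–Whitney switches to the tie-corrected normal
  approximation in the presence of ties or very large samples; a constant
  vector leaves Spearman's rho undefined (`NA`).
* Problem sizes in the test suite (e.g. 20 seeds × ~22,000 cells for
  fraction recovery, 50 master seeds for power) were chosen as the smallest
  sizes at which the sampling-theory tolerances in the tests are meaningful.

## Known limitations

* Tissue area is approximated by FOV count × FOV area; no tissue mask is
  inferred, so density is underestimated for FOVs partially filled with
  tissue.
* Thresholds are fixed by the assay design (30/100); no data-driven
  threshold estimation (Otsu, mixture models) is provided.
* Phenotyping is strictly gate-based; clustering/embedding approaches are
  out of scope, and no boundary-corrected spatial point-process statistics
  (e.g. Ripley's K) are computed beyond nearest-neighbour medians.
* The optional UMAP-style embedding stage of such analyses is decorative
  and not implemented; `select_phenotyping_targets()` provides the reduced
  target set an embedding would consume.
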
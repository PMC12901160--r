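# sscpgate

Downstream analysis of **spatial single-cell proteomics (SSCP)** experiments
— multiplexed tissue imaging runs exported as per-cell raw fluorescence
tables with centroid coordinates — aimed at quantifying the B-lineage
compartment of the colonic lamina propria (LP). It is written for
mucosal-immunology groups who receive a segmented expression matrix from the
imaging platform and need a reproducible, testable path from raw intensities
to per-patient population statistics.

## What it computes

Intestinal CD138⁺ plasma cells (PCs) mature through three stages separable
by two markers — early CD19⁺CD45⁺, intermediate CD19⁻CD45⁺, terminally
mature CD19⁻CD45⁻ — and the balance between them tracks the gut's dimeric
IgA output. For each patient the pipeline reports, among Vim⁺ LP cells
outside lymphoid follicles:

* marker-positive fractions: `100 · |Vim⁺ ∧ marker⁺| / |Vim⁺|`,
* plasmablast (PB: CD19⁺CD27⁺CD38⁺CD20⁻CD138⁻) and PC (Vim⁺CD138⁺)
  abundance, optionally rescaled so the control group's median is 1,
* PC subtype fractions over {CD19⁺CD45⁺, CD19⁻CD45⁺, CD19⁻CD45⁻, other},
  where *other* = CD19⁺CD45⁻,
* per-subtype marker summaries (median corrected level per cell, % positive,
  optionally relative to the CD19⁺CD45⁺ reference),
* nearest-epithelium distances (Euclidean, to the nearest EpCAM⁺ cell, k-d
  tree accelerated), Vim⁺ density per mm², and cell-size medians,
* two-sided Mann–Whitney case/control comparisons (exact for small tie-free
  samples), with Holm–Šídák-adjusted p values alongside unadjusted ones.

Preprocessing follows the assay design: per-cell **isotype background
subtraction** (`corrected = max(0, raw − isotype_control_of_host)`),
**positivity cut-offs** of 30 (mouse IgG1-hosted targets) and 100 (rabbit
IgG-hosted), and exclusion of 0.5 × 0.5 mm fields of view containing
lymphoid follicles.

A seeded **synthetic-tissue generator** (`synthetic_spec()`,
`generate_cohort()`) produces full cohorts with ground-truth labels —
epithelial band, LP immune mixture, planted PC-subtype fractions, lognormal
intensities with isotype-coupled background — so the entire pipeline runs
and is tested with no external data. See the methods vignette
(`vignettes/phenotyping-methods.Rmd`) for model details and design
decisions.

## Worked example

```r
library(sscpgate)

# simulate a 3 + 3 cohort and run the full pipeline on it
res <- run_pipeline(list(simulate = list(n_patients_per_condition = 3), seed = 42))
#> input: 20400 cells, 48 FOVs, 6 patients
#> follicle filter on: 16800 cells retained
#> labels: 10493 LP immune, 493 PB, 1618 PC, 4196 non-LP

head(res$pc_fractions[res$pc_fractions$patient_id == "case_01", ], 4)
#>  patient_id pc_subtype n_pc      pct
#>     case_01 CD19+CD45+  282 38.29787
#>     case_01 CD19-CD45+  282 31.91489
#>     case_01 CD19-CD45-  282 17.37589
#>     case_01      other  282 12.41135

cmp <- res$comparisons
cmp[grepl("pc_fraction", cmp$comparison), ]
#>              comparison median_case median_control U   p p_holm_sidak
#>  pc_fraction CD19+CD45+        42.6           11.9 9 0.1        0.746
#>  pc_fraction CD19-CD45+        26.4           28.5 5 1.0        1.000
#>  pc_fraction CD19-CD45-        17.1           36.1 0 0.1        0.746
#>       pc_fraction other        14.0           28.0 0 0.1        0.746

head(res$distance_medians, 4)
#>  patient_id pc_subtype   n median_distance_um
#>     case_01 CD19+CD45+ 108             183.16
#>     case_01 CD19-CD45+  90             143.47
#>     case_01 CD19-CD45-  49              70.39
#>     case_01      other  35             150.24
```

Reading the output: patient `case_01` carries 282 PCs, 38% of them still in
the early CD19⁺CD45⁺ stage. Across the cohort the early fraction is higher
in cases (median 42.6% vs 11.9%) and the mature fraction lower (17.1% vs
36.1%); with only 3 + 3 patients the smallest attainable exact two-sided
Mann–Whitney p is 0.1 (U = 9 or 0, complete separation), so nothing can
reach 0.05 at this size. The distance medians show the terminally mature
subtype sitting closest to the epithelium (70 µm vs 183 µm for early PCs),
as planted by the generator's depth bias.

Real data enter through the same interface: point `input` at a directory
with `cells.csv`, `panel.csv`, `fovs.csv` (see `read_cell_table()`,
`read_panel()`, `read_fov_annotations()` for the column contracts), with
`condition_map` translating your study's labels to case/control. A thin
command-line wrapper with `simulate` and `run` subcommands is installed at
`inst/scripts/sscp.R`.

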
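test_that("the generator is deterministic given a seed", {
  spec <- synthetic_spec(n_fovs = 2, cells_per_fov = 100, seed = 17)
  a <- generate_patient(spec, "P1", "case", seed = 17)
  b <- generate_patient(spec, "P1", "case", seed = 17)
  expect_identical(a, b)
  c2 <- generate_patient(spec, "P1", "case", seed = 18)
  expect_false(identical(a$cells, c2$cells))
})

test_that("spec validation rejects malformed fraction maps", {
  expect_error(synthetic_spec(immune_composition = c(T_CD4 = 1)),
               class = "sscp_validation_error")
  expect_error(synthetic_spec(pc_subtype_fractions = list(
    case = c("CD19+CD45+" = 0.6, "CD19-CD45+" = 0.6,
             "CD19-CD45-" = 0.1, "other" = 0.1))),
    class = "sscp_validation_error")
  expect_error(synthetic_spec(epithelial_band_frac = 1.2),
               class = "sscp_validation_error")
  spec <- synthetic_spec()
  expect_error(generate_patient(spec, "P1", "unknown_condition"),
               class = "sscp_config_error")
})

test_that("follicle flagging is an exact rounded count", {
  spec <- synthetic_spec(n_fovs = 8, follicle_fov_frac = 0.25,
                         cells_per_fov = 50, seed = 2)
  pat <- generate_patient(spec, "P1", "control")
  expect_equal(sum(pat$fovs$contains_follicle), 2L)
  # follicle FOVs carry the extra B-cell disc
  fol_fovs <- pat$fovs$fov_id[pat$fovs$contains_follicle]
  per_fov <- table(pat$cells$fov_id)
  expect_true(all(per_fov[fol_fovs] == 50 + spec$follicle_cells))
})

test_that("generated tables satisfy the package's own input validation", {
  spec <- synthetic_spec(n_fovs = 3, cells_per_fov = 150, seed = 5)
  pat <- generate_patient(spec, "P1", "case")
  expect_silent(validate_cell_table(pat$cells, spec$panel, fovs = pat$fovs))
  expect_true(all(vapply(pat$cells[gateable_targets(spec$panel)],
                         function(v) all(v >= 0), logical(1))))
})

test_that("isotype subtraction cancels the coupled background exactly", {
  # zero negative signal + unit coupling: corrected intensity must equal the
  # pure positive signal, and negative-class entries must come back exactly 0
  im <- list(pos_meanlog = log(500), pos_sdlog = 0.4,
             neg_meanlog = -Inf, neg_sdlog = 0,
             bg_meanlog = log(20), bg_sdlog = 0.6, coupling = 1)
  spec <- synthetic_spec(n_fovs = 2, cells_per_fov = 100,
                         intensity_model = im, seed = 8)
  pat <- generate_patient(spec, "P1", "case")
  corrected <- subtract_isotype_background(pat$cells, spec$panel)
  # epithelial cells express no Vimentin: exact zeros after subtraction
  epi <- pat$truth$true_class == "epithelial"
  expect_true(all(corrected$Vimentin[epi] == 0))
  expect_true(all(corrected$EpCAM[!epi] == 0))
  # reconstruction: corrected + control = raw for a mouse-hosted target
  ms <- isotype_channel(spec$panel, "mouse_IgG1")
  pospart <- corrected$CD45 > 0
  expect_equal(corrected$CD45[pospart] + pat$cells[[ms]][pospart],
               pat$cells$CD45[pospart])
})

test_that("empirical class fractions converge to the planted composition", {
  spec <- synthetic_spec(n_fovs = 8, cells_per_fov = 1700,
                         follicle_fov_frac = 0, seed = 12)
  pat <- generate_patient(spec, "P1", "case")
  lp <- pat$truth$compartment == "LP"
  expect_gt(sum(lp), 10000)
  emp <- table(pat$truth$true_class[lp]) / sum(lp)
  for (cl in IMMUNE_CLASSES) {
    expect_lt(abs(emp[[cl]] - spec$immune_composition[[cl]]), 0.015)
  }
})

test_that("the distance bias plants the subtype ordering near the epithelium", {
  hits <- 0L
  n_seeds <- 12L
  for (s in seq_len(n_seeds)) {
    spec <- synthetic_spec(n_fovs = 4, cells_per_fov = 600,
                           follicle_fov_frac = 0, seed = 100 + s)
    pat <- generate_patient(spec, "P1", "case", seed = 100 + s)
    pos <- call_positivity(pat$cells, spec$panel)
    lab <- classify_cells(pos)
    d <- nearest_epithelium_distance(pat$cells, pos, lab)
    m <- median_distance_per_subtype(d)
    m1 <- m$median_distance_um[m$pc_subtype == "CD19-CD45-"]
    others <- m$median_distance_um[m$pc_subtype %in% c("CD19+CD45+", "CD19-CD45+")]
    if (length(m1) == 1 && all(m1 < others)) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.95 * n_seeds))
})

test_that("cohorts are reproducible piecewise and round-trip through the container", {
  spec <- synthetic_spec(n_patients_per_condition = 2, n_fovs = 2,
                         cells_per_fov = 80, seed = 9)
  dir <- withr::local_tempdir()
  coh <- generate_cohort(spec, out_dir = dir)
  expect_setequal(unique(coh$cells$condition), c("case", "control"))
  expect_equal(length(unique(coh$cells$patient_id)), 4L)

  # patient 3 (control_01) regenerates in isolation from the derived seed
  s3 <- (9 * 1000 + 3) %% 2147483647
  pat <- generate_patient(spec, "control_01", "control", seed = s3)
  sub <- coh$cells[coh$cells$patient_id == "control_01", , drop = FALSE]
  rownames(sub) <- NULL
  expect_identical(pat$cells, sub)

  # written container reads back bit-identically
  panel <- read_panel(file.path(dir, "panel.csv"))
  fovs <- read_fov_annotations(file.path(dir, "control_01", "fovs.csv"))
  back <- read_cell_table(file.path(dir, "control_01", "cells.csv"), panel,
                          fovs = fovs)
  expect_equal(back$x_um, pat$cells$x_um)
  expect_equal(back$CD38, pat$cells$CD38)
})
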
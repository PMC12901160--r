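# helper: minimal cells/positivity/labels for distance tests
dist_fixture <- function(ax, ay, qx, qy, patient = "P1") {
  na <- length(ax); nq <- length(qx)
  cells <- data.frame(
    cell_id = sprintf("c%03d", seq_len(na + nq)),
    patient_id = patient, condition = "case", fov_id = "F1",
    x_um = c(ax, qx), y_um = c(ay, qy), area_um2 = 100,
    stringsAsFactors = FALSE)
  pos <- matrix(FALSE, na + nq, 3,
                dimnames = list(cells$cell_id, c("EpCAM", "Vimentin", "CD138")))
  pos[seq_len(na), "EpCAM"] <- TRUE
  lab <- data.frame(
    cell_id = cells$cell_id,
    lineage = factor(rep(c("non_LP", "PC"), c(na, nq)),
                     levels = c("LP_immune", "non_LP", "PB", "PC")),
    pc_subtype = factor(rep(c("not_a_PC", "CD19+CD45+"), c(na, nq)),
                        levels = c(PC_SUBTYPES, "not_a_PC")),
    stringsAsFactors = FALSE)
  list(cells = cells, pos = pos, lab = lab)
}

test_that("nearest-epithelium distance is plain Euclidean geometry", {
  fx <- dist_fixture(ax = 0, ay = 0, qx = c(3, 0), qy = c(4, 0))
  d <- nearest_epithelium_distance(fx$cells, fx$pos, fx$lab)
  expect_equal(d$distance_um, c(5, 0))

  # patient with no EpCAM+ cells: NA with warning
  fx$pos[, "EpCAM"] <- FALSE
  expect_warning(d <- nearest_epithelium_distance(fx$cells, fx$pos, fx$lab),
                 "no EpCAM")
  expect_true(all(is.na(d$distance_um)))
})

test_that("k-d tree distances equal the exhaustive scan", {
  set.seed(5)
  n <- 300
  fx <- dist_fixture(ax = runif(n, 0, 4000), ay = runif(n, 0, 500),
                     qx = runif(n, 0, 4000), qy = runif(n, 0, 500))
  kd <- nearest_epithelium_distance(fx$cells, fx$pos, fx$lab, method = "kdtree")
  br <- nearest_epithelium_distance(fx$cells, fx$pos, fx$lab, method = "brute")
  expect_lt(max(abs(kd$distance_um - br$distance_um)), 1e-9)
})

test_that("distances are invariant under rigid motions of a patient's slide", {
  set.seed(6)
  fx <- dist_fixture(ax = runif(50, 0, 1000), ay = runif(50, 0, 1000),
                     qx = runif(50, 0, 1000), qy = runif(50, 0, 1000))
  d0 <- nearest_epithelium_distance(fx$cells, fx$pos, fx$lab)$distance_um
  th <- 0.7
  rot <- fx$cells
  rot$x_um <- cos(th) * fx$cells$x_um - sin(th) * fx$cells$y_um + 12345
  rot$y_um <- sin(th) * fx$cells$x_um + cos(th) * fx$cells$y_um - 678
  d1 <- nearest_epithelium_distance(rot, fx$pos, fx$lab)$distance_um
  expect_equal(d1, d0, tolerance = 1e-9)
})

test_that("per-subtype distance medians aggregate correctly", {
  rec <- data.frame(cell_id = sprintf("c%d", 1:4), patient_id = "P1", fov_id = "F1",
                    pc_subtype = c(rep("CD19+CD45+", 3), "CD19-CD45-"),
                    distance_um = c(1, 2, 9, 42), stringsAsFactors = FALSE)
  m <- median_distance_per_subtype(rec)
  expect_equal(m$median_distance_um[m$pc_subtype == "CD19+CD45+"], 2)
  expect_equal(m$median_distance_um[m$pc_subtype == "CD19-CD45-"], 42)
  expect_equal(m$n, c(3L, 1L))
})

test_that("LP density is count over retained-FOV area and scales with side", {
  fovs <- tiny_fovs(paste0("F", 1:8))
  cells <- data.frame(cell_id = sprintf("c%d", 1:600), patient_id = "P1",
                      condition = "case", fov_id = rep(paste0("F", 1:8), 75),
                      x_um = 1, y_um = 1, area_um2 = 100, stringsAsFactors = FALSE)
  lab <- data.frame(cell_id = cells$cell_id,
                    lineage = factor("LP_immune",
                                     levels = c("LP_immune", "non_LP", "PB", "PC")),
                    pc_subtype = factor("not_a_PC",
                                        levels = c(PC_SUBTYPES, "not_a_PC")))
  d <- lp_cell_density(cells, fovs, lab)
  expect_equal(d$density_per_mm2, 300)   # 600 cells over 8 x 0.25 mm^2

  half <- fovs; half$side_um <- 250
  expect_equal(lp_cell_density(cells, half, lab)$density_per_mm2, 1200)

  lab0 <- lab; lab0$lineage[] <- "non_LP"
  expect_equal(lp_cell_density(cells, fovs, lab0)$density_per_mm2, 0)

  allfol <- fovs; allfol$contains_follicle <- TRUE
  expect_warning(d0 <- lp_cell_density(cells, allfol, lab), "no retained FOVs")
  expect_true(is.na(d0$density_per_mm2))
})

test_that("cell-size summaries are per-subtype medians and optional", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:4), patient_id = "P1",
                      condition = "case", fov_id = "F1", x_um = 0, y_um = 0,
                      area_um2 = c(100, 120, 140, 90), stringsAsFactors = FALSE)
  lab <- data.frame(cell_id = cells$cell_id,
                    lineage = factor(c("PC", "PC", "PC", "PC"),
                                     levels = c("LP_immune", "non_LP", "PB", "PC")),
                    pc_subtype = factor(c(rep("CD19+CD45+", 3), "CD19-CD45-"),
                                        levels = c(PC_SUBTYPES, "not_a_PC")))
  s <- cell_size_summary(cells, lab)
  expect_equal(s$median_area_um2[s$pc_subtype == "CD19+CD45+"], 120)
  expect_equal(s$median_area_um2[s$pc_subtype == "CD19-CD45-"], 90)

  noarea <- cells[, setdiff(names(cells), "area_um2")]
  expect_warning(out <- cell_size_summary(noarea, lab), "skipped")
  expect_null(out)
})
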
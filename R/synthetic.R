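# Synthetic-tissue generator: seeded per-patient cell tables with known
# ground truth, emulating the statistical structure the analysis assumes —
# a 64-plex panel with isotype-control channels, 0.5 x 0.5 mm FOVs laid in a
# strip, a contiguous epithelial band (EpCAM+/PanCK+, Vim-) above a
# lamina-propria compartment (Vim+) of T/DC/NK/B cells, plasmablasts and
# plasma-cell subtypes at planted per-condition fractions, lognormal marker
# intensities with isotype-coupled background, and optional follicle FOVs
# carrying a dense B-cell disc.

IMMUNE_CLASSES <- c("T_CD4", "T_CD8", "DC", "NK", "B", "PB", "PC")

.default_composition <- function() {
  c(T_CD4 = 0.30, T_CD8 = 0.18, DC = 0.16, NK = 0.10,
    B = 0.10, PB = 0.04, PC = 0.12)
}

.default_pc_fractions <- function() {
  list(case    = c("CD19+CD45+" = 0.446, "CD19-CD45+" = 0.250,
                   "CD19-CD45-" = 0.155, "other" = 0.149),
       control = c("CD19+CD45+" = 0.132, "CD19-CD45+" = 0.300,
                   "CD19-CD45-" = 0.327, "other" = 0.241))
}

# Lognormal intensity families on the fluorescence scale of the 30/100
# cut-offs: positive signal well above both, negative signal plus coupled
# background well below the mouse cut-off.
.default_intensity_model <- function() {
  list(pos_meanlog = log(400), pos_sdlog = 0.5,
       neg_meanlog = log(3),   neg_sdlog = 0.7,
       bg_meanlog  = log(5),   bg_sdlog  = 0.5,
       coupling = 1)
}

# Degenerate-noise preset: positive signal orders of magnitude above the
# cut-offs, zero negative signal and zero background, so every truth label is
# recoverable exactly.
.separation_intensity_model <- function() {
  list(pos_meanlog = log(5000), pos_sdlog = 0.15,
       neg_meanlog = -Inf, neg_sdlog = 0,
       bg_meanlog = -Inf, bg_sdlog = 0,
       coupling = 1)
}

#' Parameters of the synthetic-tissue generator
#'
#' Returns a validated specification; every default is chosen once to mirror
#' a small colonic-biopsy imaging study (see the methods vignette for the
#' rationale behind each value). `preset = "separation"` swaps in a
#' noise-free intensity model under which downstream gating must recover the
#' ground truth exactly.
#'
#' @param n_patients_per_condition patients per condition (default 6 + 6).
#' @param n_fovs FOVs per patient, laid in a single row so the epithelial
#'   band is contiguous.
#' @param fov_side_um FOV edge length (default 500 um = 0.5 mm).
#' @param cells_per_fov cells per FOV before any follicle disc is added.
#' @param epithelial_band_frac fraction of FOV height (and of cells) occupied
#'   by the epithelial band at the top of each FOV.
#' @param follicle_fov_frac fraction of FOVs flagged `contains_follicle`
#'   (count is rounded, so 0.25 of 8 FOVs flags exactly 2).
#' @param follicle_cells extra B cells planted in each follicle disc.
#' @param immune_composition named fractions over
#'   `T_CD4, T_CD8, DC, NK, B, PB, PC` among Vim+ LP cells; must sum to 1.
#' @param pc_subtype_fractions named list (one entry per condition) of
#'   fractions over the four PC subtypes; each must sum to 1. Defaults echo
#'   an early-shifted case group versus a mature-shifted control group.
#' @param intensity_model list with `pos_meanlog`, `pos_sdlog`,
#'   `neg_meanlog`, `neg_sdlog`, `bg_meanlog`, `bg_sdlog`, `coupling`. Raw
#'   intensity = class-appropriate lognormal signal + `coupling` x the cell's
#'   host-matched isotype background draw; the control channels carry the
#'   pure background draw, so subtraction cancels it exactly when
#'   `coupling = 1`.
#' @param subtype_distance_bias named positive numbers; subtype `s` with bias
#'   `b > 1` has its LP depth drawn from Beta(1, b) instead of uniform,
#'   pulling it toward the epithelial band. Default pulls the terminally
#'   mature CD19-CD45- subtype epithelium-ward.
#' @param panel the `sscp_panel` to simulate (default [default_panel()]).
#' @param seed master seed; per-patient seeds are derived from it (see
#'   [generate_cohort()]).
#' @param preset `NULL` or `"separation"`.
#' @return list of class `sscp_synth_spec`.
#' @export
synthetic_spec <- function(n_patients_per_condition = 6L,
                           n_fovs = 8L,
                           fov_side_um = 500,
                           cells_per_fov = 400L,
                           epithelial_band_frac = 0.25,
                           follicle_fov_frac = 0.125,
                           follicle_cells = 200L,
                           immune_composition = .default_composition(),
                           pc_subtype_fractions = .default_pc_fractions(),
                           intensity_model = .default_intensity_model(),
                           subtype_distance_bias = c("CD19-CD45-" = 3),
                           panel = default_panel(),
                           seed = 1L,
                           preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "separation")
    intensity_model <- .separation_intensity_model()
  }
  # tolerate YAML-style nested lists for the numeric maps
  immune_composition <- unlist(immune_composition)
  if (is.list(pc_subtype_fractions)) {
    pc_subtype_fractions <- lapply(pc_subtype_fractions, unlist)
  }
  subtype_distance_bias <- unlist(subtype_distance_bias)
  .check_fractions(immune_composition, IMMUNE_CLASSES, "immune_composition")
  if (!is.list(pc_subtype_fractions) || is.null(names(pc_subtype_fractions))) {
    abort_validation("pc_subtype_fractions must be a named list (one entry per condition)")
  }
  for (cond in names(pc_subtype_fractions)) {
    .check_fractions(pc_subtype_fractions[[cond]], PC_SUBTYPES,
                     paste0("pc_subtype_fractions$", cond))
  }
  if (epithelial_band_frac <= 0 || epithelial_band_frac >= 1) {
    abort_validation("epithelial_band_frac must be in (0, 1)")
  }
  if (follicle_fov_frac < 0 || follicle_fov_frac > 1) {
    abort_validation("follicle_fov_frac must be in [0, 1]")
  }
  need_im <- c("pos_meanlog", "pos_sdlog", "neg_meanlog", "neg_sdlog",
               "bg_meanlog", "bg_sdlog", "coupling")
  miss <- setdiff(need_im, names(intensity_model))
  if (length(miss)) {
    abort_validation(paste0("intensity_model missing: ", paste(miss, collapse = ", ")))
  }
  structure(list(
    n_patients_per_condition = as.integer(n_patients_per_condition),
    n_fovs = as.integer(n_fovs), fov_side_um = fov_side_um,
    cells_per_fov = as.integer(cells_per_fov),
    epithelial_band_frac = epithelial_band_frac,
    follicle_fov_frac = follicle_fov_frac,
    follicle_cells = as.integer(follicle_cells),
    immune_composition = immune_composition,
    pc_subtype_fractions = pc_subtype_fractions,
    intensity_model = intensity_model,
    subtype_distance_bias = subtype_distance_bias,
    panel = panel, seed = as.integer(seed)), class = "sscp_synth_spec")
}

.check_fractions <- function(fr, classes, what) {
  if (!setequal(names(fr), classes)) {
    abort_validation(paste0(what, " must be named over: ", paste(classes, collapse = ", ")))
  }
  if (any(fr < 0) || abs(sum(fr) - 1) > 1e-9) {
    abort_validation(paste0(what, " fractions must be nonnegative and sum to 1"))
  }
  fr[classes]
}

# Per-class marker programmes: probability of expressing each target and a
# multiplicative level factor applied to the positive signal. Classes for PC
# subtypes are keyed "PC:<subtype>".
.class_profiles <- function(panel) {
  targets <- gateable_targets(panel)
  classes <- c("epithelial", "T_CD4", "T_CD8", "DC", "NK", "B", "PB",
               paste0("PC:", PC_SUBTYPES))
  prob <- matrix(0, length(classes), length(targets),
                 dimnames = list(classes, targets))
  mult <- matrix(1, length(classes), length(targets),
                 dimnames = list(classes, targets))

  set_pos <- function(cls, tg, p = 1) {
    tg <- intersect(tg, targets)
    prob[cls, tg] <<- p
  }

  set_pos("epithelial", c("EpCAM", "PanCK", "B2M", "CD298", "Beta-catenin", "EGFR"))
  immune_base <- c("Vimentin", "B2M", "CD298")
  for (cls in setdiff(classes, "epithelial")) set_pos(cls, immune_base)
  for (cls in c("T_CD4", "T_CD8", "DC", "NK", "B", "PB")) set_pos(cls, "CD45")

  set_pos("T_CD4", c("CD3", "CD4", "CD127"))
  set_pos("T_CD8", c("CD3", "CD8", "Granzyme B"))
  set_pos("DC", c("CD11c", "HLA-DR", "CD14"))
  set_pos("NK", c("CD56", "Granzyme B"))
  set_pos("B", c("CD19", "CD20", "CD21", "HLA-DR"))
  set_pos("B", "CD27", 0.5)     # mixed naive/memory
  set_pos("B", "IgD", 0.5)
  set_pos("PB", c("CD19", "CD27", "CD38", "HLA-DR"))
  set_pos("PB", "Ki-67", 0.6)

  pc_common <- c("Vimentin", "B2M", "CD298", "CD138", "CD38", "CD27", "Bcl-2",
                 "NF-kB p65", "pan-RAS")
  ki67 <- c("CD19+CD45+" = 0.30, "CD19-CD45+" = 0.10,
            "CD19-CD45-" = 0.03, "other" = 0.10)
  # Graded levels along maturation: CD38 and CD138 decline slightly; the
  # activating signalling proteins NF-kB p65 and pan-RAS step down.
  grade <- list(
    "CD38"      = c(1, 0.80, 0.60, 0.80),
    "CD138"     = c(1, 0.95, 0.90, 0.95),
    "NF-kB p65" = c(1, 0.50, 0.45, 0.70),
    "pan-RAS"   = c(1, 0.90, 0.45, 0.90))
  sub_signs <- list("CD19+CD45+" = c("CD19", "CD45"),
                    "CD19-CD45+" = "CD45",
                    "CD19-CD45-" = character(0),
                    "other"      = "CD19")   # the omitted CD19+CD45- combination
  for (i in seq_along(PC_SUBTYPES)) {
    s <- PC_SUBTYPES[i]
    cls <- paste0("PC:", s)
    set_pos(cls, pc_common)
    set_pos(cls, "Ki-67", ki67[[s]])
    set_pos(cls, sub_signs[[s]])
    for (tg in names(grade)) if (tg %in% targets) mult[cls, tg] <- grade[[tg]][i]
  }
  list(prob = prob, mult = mult, classes = classes, targets = targets)
}

# Median cell areas (um^2) per class; PC subtypes grow slightly along
# maturation (secretory organelle expansion).
.area_meanlog <- function(class_key) {
  base <- c(epithelial = log(70), T_CD4 = log(55), T_CD8 = log(55),
            DC = log(60), NK = log(55), B = log(60), PB = log(90),
            "PC:CD19+CD45+" = log(100), "PC:CD19-CD45+" = log(110),
            "PC:CD19-CD45-" = log(120), "PC:other" = log(105))
  unname(base[class_key])
}

#' Generate one synthetic patient
#'
#' Lays `n_fovs` FOVs in a row, fills the top `epithelial_band_frac` of each
#' with epithelial cells and the rest with Vim+ LP cells drawn from
#' `immune_composition` (PC subtypes from the condition's planted fractions),
#' plants a dense B-cell disc in follicle-flagged FOVs, and draws raw
#' intensities as lognormal signal plus isotype-coupled background. Output is
#' fully determined by `seed`.
#'
#' @param spec an `sscp_synth_spec`.
#' @param patient_id patient identifier.
#' @param condition one of `names(spec$pc_subtype_fractions)`.
#' @param seed integer seed for this patient (default: the spec's master seed).
#' @return list with `cells` (cell table), `fovs` (annotations) and `truth`
#'   (`cell_id`, `true_class`, `true_pc_subtype`, `compartment`).
#' @export
generate_patient <- function(spec, patient_id, condition, seed = spec$seed) {
  stopifnot(inherits(spec, "sscp_synth_spec"))
  if (!condition %in% names(spec$pc_subtype_fractions)) {
    abort_config(paste0("condition '", condition, "' has no planted PC subtype fractions"))
  }
  set.seed(seed)
  side <- spec$fov_side_um
  band <- spec$epithelial_band_frac
  lp_h <- side * (1 - band)
  nf <- spec$n_fovs

  fovs <- data.frame(
    fov_id = sprintf("%s_F%02d", patient_id, seq_len(nf)),
    patient_id = patient_id,
    origin_x_um = (seq_len(nf) - 1) * side,
    origin_y_um = 0,
    side_um = side,
    contains_follicle = FALSE,
    stringsAsFactors = FALSE)
  n_fol <- round(spec$follicle_fov_frac * nf)
  if (n_fol > 0) fovs$contains_follicle[sample(nf, n_fol)] <- TRUE

  n_epi <- round(band * spec$cells_per_fov)
  n_lp <- spec$cells_per_fov - n_epi

  fov_idx <- rep(seq_len(nf), each = spec$cells_per_fov)
  compartment <- rep(rep(c("epithelium", "LP"), c(n_epi, n_lp)), nf)
  class_key <- ifelse(compartment == "epithelium", "epithelial", NA)

  lp_sel <- compartment == "LP"
  lp_class <- sample(IMMUNE_CLASSES, sum(lp_sel), replace = TRUE,
                     prob = spec$immune_composition[IMMUNE_CLASSES])
  pc_sel <- lp_class == "PC"
  fr <- spec$pc_subtype_fractions[[condition]][PC_SUBTYPES]
  lp_class[pc_sel] <- paste0("PC:", sample(PC_SUBTYPES, sum(pc_sel),
                                           replace = TRUE, prob = fr))
  class_key[lp_sel] <- lp_class

  # follicle discs: extra B cells appended per flagged FOV
  for (f in which(fovs$contains_follicle)) {
    nfc <- spec$follicle_cells
    if (nfc == 0) next
    fov_idx <- c(fov_idx, rep(f, nfc))
    compartment <- c(compartment, rep("follicle", nfc))
    class_key <- c(class_key, rep("B", nfc))
  }
  n <- length(fov_idx)
  ox <- fovs$origin_x_um[fov_idx]

  # positions: epithelial band at the top of each FOV, LP below; biased PC
  # subtypes sit at shallower LP depths (closer to the band)
  x <- ox + stats::runif(n) * side
  y <- numeric(n)
  epi <- compartment == "epithelium"
  y[epi] <- lp_h + stats::runif(sum(epi)) * side * band
  lp <- compartment == "LP"
  u <- stats::runif(sum(lp))
  lp_keys <- class_key[lp]
  for (s in names(spec$subtype_distance_bias)) {
    i <- lp_keys == paste0("PC:", s)
    if (any(i)) u[i] <- stats::rbeta(sum(i), 1, spec$subtype_distance_bias[[s]])
  }
  y[lp] <- lp_h * (1 - u)
  fol <- compartment == "follicle"
  if (any(fol)) {
    for (f in unique(fov_idx[fol])) {
      i <- which(fol & fov_idx == f)
      cx <- fovs$origin_x_um[f] + side * (0.3 + 0.4 * stats::runif(1))
      cy <- lp_h * (0.25 + 0.4 * stats::runif(1))
      r <- 0.15 * side * sqrt(stats::runif(length(i)))
      th <- 2 * pi * stats::runif(length(i))
      x[i] <- pmin(pmax(cx + r * cos(th), fovs$origin_x_um[f]),
                   fovs$origin_x_um[f] + side * (1 - 1e-9))
      y[i] <- pmin(pmax(cy + r * sin(th), 0), lp_h * (1 - 1e-9))
    }
  }

  # intensities
  pr <- .class_profiles(spec$panel)
  im <- spec$intensity_model
  ci <- match(class_key, pr$classes)
  nt <- length(pr$targets)
  P <- pr$prob[ci, , drop = FALSE]
  logmult <- log(pr$mult[ci, , drop = FALSE])
  pos <- matrix(stats::runif(n * nt), n, nt) < P
  meanlog <- ifelse(pos, im$pos_meanlog + logmult, im$neg_meanlog)
  sdlog <- ifelse(pos, im$pos_sdlog, im$neg_sdlog)
  signal <- matrix(.rlnorm_safe(n * nt, as.vector(meanlog), as.vector(sdlog)), n, nt)
  colnames(signal) <- pr$targets

  hosts <- target_hosts(spec$panel)
  host_levels <- unique(unname(hosts))
  bg <- vapply(host_levels, function(h) .rlnorm_safe(n, im$bg_meanlog, im$bg_sdlog),
               numeric(n))
  if (n == 1L) bg <- matrix(bg, nrow = 1, dimnames = list(NULL, host_levels))
  raw <- signal + im$coupling * bg[, hosts[pr$targets], drop = FALSE]

  area <- .rlnorm_safe(n, .area_meanlog(class_key), 0.2)

  cells <- data.frame(
    cell_id = sprintf("%s_c%06d", patient_id, seq_len(n)),
    patient_id = patient_id, condition = condition,
    fov_id = fovs$fov_id[fov_idx],
    x_um = x, y_um = y, area_um2 = area,
    stringsAsFactors = FALSE, check.names = FALSE)
  for (t in spec$panel$targets$name) {
    cells[[t]] <- if (t %in% pr$targets) raw[, t] else bg[, hosts[[t]]]
  }

  truth <- data.frame(
    cell_id = cells$cell_id, patient_id = patient_id,
    true_class = sub(":.*$", "", sub("^PC:.*$", "PC", class_key)),
    true_pc_subtype = ifelse(startsWith(class_key, "PC:"),
                             sub("^PC:", "", class_key), "not_a_PC"),
    compartment = compartment, stringsAsFactors = FALSE)

  list(cells = cells, fovs = fovs, truth = truth)
}

# rlnorm tolerating meanlog = -Inf (exact zeros) and sdlog = 0 (degenerate).
.rlnorm_safe <- function(n, meanlog, sdlog) {
  z <- stats::rnorm(n)
  out <- exp(meanlog + sdlog * z)
  out[is.nan(out)] <- 0
  out
}

#' Map ground-truth classes to the labels the pipeline should assign
#'
#' Epithelial cells are outside the lamina propria (`non_LP`); T/DC/NK/B
#' cells are generic `LP_immune`; PBs and PCs map to themselves.
#'
#' @param truth truth table from [generate_patient()].
#' @return data frame `cell_id`, `lineage`, `pc_subtype` in truth row order.
#' @export
expected_labels_from_truth <- function(truth) {
  lin <- c(epithelial = "non_LP", T_CD4 = "LP_immune", T_CD8 = "LP_immune",
           DC = "LP_immune", NK = "LP_immune", B = "LP_immune",
           PB = "PB", PC = "PC")
  data.frame(cell_id = truth$cell_id,
             lineage = unname(lin[truth$true_class]),
             pc_subtype = truth$true_pc_subtype,
             stringsAsFactors = FALSE)
}

#' Generate a full two-condition cohort
#'
#' One patient per `condition x index`; the per-patient seed is derived from
#' the master seed by the documented rule
#' `(master * 1000 + running_index) mod (2^31 - 1)`, so any patient can be
#' regenerated in isolation.
#'
#' @param spec an `sscp_synth_spec`.
#' @param out_dir optional directory; when given, each patient's
#'   `cells.csv`, `fovs.csv`, `truth.csv` plus a shared `panel.csv` are
#'   written under `<out_dir>/<patient_id>/`.
#' @return list with pooled `cells`, `fovs`, `truth`, the `panel` and the
#'   `spec`.
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "sscp_synth_spec"))
  conditions <- names(spec$pc_subtype_fractions)
  cells <- fovs <- truth <- list()
  idx <- 0L
  for (cond in conditions) {
    for (i in seq_len(spec$n_patients_per_condition)) {
      idx <- idx + 1L
      pid <- sprintf("%s_%02d", cond, i)
      s <- (as.numeric(spec$seed) * 1000 + idx) %% 2147483647
      pat <- generate_patient(spec, pid, cond, seed = s)
      cells[[pid]] <- pat$cells
      fovs[[pid]] <- pat$fovs
      truth[[pid]] <- pat$truth
      if (!is.null(out_dir)) {
        d <- file.path(out_dir, pid)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        write_cell_table(pat$cells, file.path(d, "cells.csv"))
        write_fov_annotations(pat$fovs, file.path(d, "fovs.csv"))
        .write_table(pat$truth, file.path(d, "truth.csv"))
      }
    }
  }
  if (!is.null(out_dir)) write_panel(spec$panel, file.path(out_dir, "panel.csv"))
  out <- list(cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
              fovs = do.call(rbind, c(fovs, list(make.row.names = FALSE))),
              truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
              panel = spec$panel, spec = spec)
  out
}
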
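# Hierarchical phenotyping of lamina-propria cells into B-lineage populations
# and plasma-cell maturation subtypes, plus the per-patient fraction,
# abundance and marker summaries reported on top of the labels.

#' Plasma-cell maturation subtype labels, in maturation order
#' @export
PC_SUBTYPES <- c("CD19+CD45+", "CD19-CD45+", "CD19-CD45-", "other")

#' Classify cells into B-lineage populations and PC subtypes
#'
#' Hierarchy: Vimentin+ CD138+ cells are plasma cells (PC); Vimentin+ cells
#' matching the plasmablast gate (CD19+ CD27+ CD38+ CD20- CD138-) are PBs;
#' remaining Vimentin+ cells are generic LP immune cells; Vimentin- cells are
#' outside the lamina propria (`non_LP`). PCs are subtyped by their CD19/CD45
#' signs: CD19+CD45+ (early), CD19-CD45+ (intermediate), CD19-CD45-
#' (terminally mature), and CD19+CD45- as `other`, the one combination the
#' three named subtypes omit.
#'
#' @param positivity logical positivity matrix from [call_positivity()].
#' @param gates gate library; must contain `LP_immune`, `PC` and `PB` gates.
#' @param subtype_markers the two markers whose signs define the PC subtypes.
#' @return data frame with `cell_id`, `lineage`
#'   (factor: `LP_immune`, `non_LP`, `PB`, `PC`) and `pc_subtype`
#'   (factor over [PC_SUBTYPES] plus `not_a_PC`), aligned to the rows of
#'   `positivity`.
#' @export
classify_cells <- function(positivity, gates = default_gates(),
                           subtype_markers = c("CD19", "CD45")) {
  need <- c("LP_immune", "PC", "PB")
  miss <- setdiff(need, names(gates))
  if (length(miss)) {
    abort_config(paste0("gate library missing gate(s): ", paste(miss, collapse = ", ")))
  }
  miss_m <- setdiff(subtype_markers, colnames(positivity))
  if (length(miss_m)) {
    abort_config(paste0("positivity matrix lacks subtype marker(s): ",
                        paste(miss_m, collapse = ", ")))
  }

  is_lp <- evaluate_gate(positivity, gates$LP_immune)
  is_pc <- evaluate_gate(positivity, gates$PC)
  is_pb <- evaluate_gate(positivity, gates$PB) & !is_pc

  lineage <- rep("non_LP", nrow(positivity))
  lineage[is_lp] <- "LP_immune"
  lineage[is_pb] <- "PB"
  lineage[is_pc] <- "PC"

  m1 <- positivity[, subtype_markers[1]]
  m2 <- positivity[, subtype_markers[2]]
  pc_subtype <- rep("not_a_PC", nrow(positivity))
  pc_subtype[is_pc &  m1 &  m2] <- PC_SUBTYPES[1]
  pc_subtype[is_pc & !m1 &  m2] <- PC_SUBTYPES[2]
  pc_subtype[is_pc & !m1 & !m2] <- PC_SUBTYPES[3]
  pc_subtype[is_pc &  m1 & !m2] <- PC_SUBTYPES[4]

  data.frame(
    cell_id = rownames(positivity) %||% as.character(seq_len(nrow(positivity))),
    lineage = factor(lineage, levels = c("LP_immune", "non_LP", "PB", "PC")),
    pc_subtype = factor(pc_subtype, levels = c(PC_SUBTYPES, "not_a_PC")),
    stringsAsFactors = FALSE)
}

# Vim+ LP residency = any lineage other than non_LP (PB and PC are Vim+ by gate).
.is_vim_lp <- function(labels) labels$lineage != "non_LP"

#' Per-patient marker-positive fractions of Vim+ LP cells
#'
#' For each patient and each target, the percentage of Vimentin+ LP cells
#' positive for that target (counts are normalised to total Vim+ LP cells to
#' absorb differences in tissue area and cell density). Patients without a
#' single Vim+ cell get `NA`, not 0.
#'
#' @param cells cell table aligned with `positivity`/`labels` (only
#'   `patient_id` is used).
#' @param positivity logical positivity matrix.
#' @param labels output of [classify_cells()].
#' @param targets targets to report; defaults to every positivity column.
#' @return long data frame: `patient_id`, `target`, `pct` (0-100).
#' @export
marker_fractions <- function(cells, positivity, labels,
                             targets = colnames(positivity)) {
  stopifnot(nrow(cells) == nrow(positivity), nrow(cells) == nrow(labels))
  miss <- setdiff(targets, colnames(positivity))
  if (length(miss)) {
    abort_config(paste0("unknown target(s): ", paste(miss, collapse = ", ")))
  }
  vim <- .is_vim_lp(labels)
  pats <- unique(cells$patient_id)
  out <- vector("list", length(pats))
  for (k in seq_along(pats)) {
    sel <- cells$patient_id == pats[k] & vim
    n <- sum(sel)
    if (n == 0L) {
      warning(paste0("patient ", pats[k], " has no Vim+ LP cells; fractions undefined"))
      pct <- rep(NA_real_, length(targets))
    } else {
      pct <- 100 * colSums(positivity[sel, targets, drop = FALSE]) / n
    }
    out[[k]] <- data.frame(patient_id = pats[k], target = targets,
                           n_vim = n, pct = unname(pct),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Per-patient plasma-cell subtype fractions
#'
#' Percentage of each patient's CD138+ PCs falling in each of the four
#' CD19/CD45 subtypes; the four fractions sum to 100 whenever the patient has
#' at least one PC, and are `NA` otherwise.
#'
#' @inheritParams marker_fractions
#' @return long data frame: `patient_id`, `pc_subtype`, `n_pc`, `pct`.
#' @export
pc_subtype_fractions <- function(cells, labels) {
  stopifnot(nrow(cells) == nrow(labels))
  pats <- unique(cells$patient_id)
  out <- vector("list", length(pats))
  is_pc <- labels$lineage == "PC"
  for (k in seq_along(pats)) {
    sel <- cells$patient_id == pats[k] & is_pc
    n <- sum(sel)
    if (n == 0L) {
      warning(paste0("patient ", pats[k], " has no PCs; subtype fractions undefined"))
      pct <- rep(NA_real_, length(PC_SUBTYPES))
    } else {
      cnt <- table(factor(labels$pc_subtype[sel], levels = PC_SUBTYPES))
      pct <- 100 * as.numeric(cnt) / n
    }
    out[[k]] <- data.frame(patient_id = pats[k], pc_subtype = PC_SUBTYPES,
                           n_pc = n, pct = pct, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Scale per-patient statistics so the control-group median is 1
#'
#' @param case_values numeric vector of the case group's per-patient values.
#' @param control_values numeric vector for the control group; its median
#'   must be nonzero (the scale is undefined otherwise).
#' @return list with rescaled `case` and `control` vectors and the
#'   `control_median` used.
#' @export
relative_abundance <- function(case_values, control_values) {
  control_values <- control_values[!is.na(control_values)]
  if (length(control_values) == 0L) abort_validation("control group is empty")
  med <- stats::median(control_values)
  if (!is.finite(med) || med == 0) {
    abort_validation("control-group median is zero; relative abundance undefined")
  }
  list(case = case_values / med, control = control_values / med,
       control_median = med)
}

#' Per-subtype marker summaries (median level, percent positive)
#'
#' For each patient x PC subtype x target: the median background-corrected
#' intensity per cell and the percentage of positive cells — the two numbers
#' behind a dot-plot summary (circle colour and circle size). With a
#' `reference` subtype, both are additionally divided by the patient's value
#' in that subtype, so the reference row is 1 by construction.
#'
#' @param corrected isotype-subtracted cell table (see
#'   [subtract_isotype_background()]); a raw table triggers a warning.
#' @param positivity positivity matrix aligned with `corrected`.
#' @param labels output of [classify_cells()] aligned with `corrected`.
#' @param targets targets to summarise, e.g.
#'   [select_phenotyping_targets()]; defaults to every positivity column.
#' @param reference optional reference subtype (one of [PC_SUBTYPES]); every
#'   patient must have at least one cell of it.
#' @return long data frame: `patient_id`, `pc_subtype`, `target`, `n_cells`,
#'   `median_level`, `pct_positive` and, when `reference` is given,
#'   `rel_median_level`, `rel_pct_positive`.
#' @export
subtype_marker_summary <- function(corrected, positivity, labels,
                                   targets = colnames(positivity),
                                   reference = NULL) {
  stopifnot(nrow(corrected) == nrow(positivity), nrow(corrected) == nrow(labels))
  if (!isTRUE(attr(corrected, "isotype_subtracted"))) {
    warning("summarising raw (not isotype-subtracted) intensities")
  }
  miss <- setdiff(targets, intersect(colnames(positivity), names(corrected)))
  if (length(miss)) {
    abort_config(paste0("unknown target(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.null(reference) && !reference %in% PC_SUBTYPES) {
    abort_config(paste0("reference must be one of: ", paste(PC_SUBTYPES, collapse = ", ")))
  }

  pats <- unique(corrected$patient_id)
  rows <- list()
  for (p in pats) {
    per_sub <- list()
    for (s in PC_SUBTYPES) {
      sel <- corrected$patient_id == p & labels$pc_subtype == s
      n <- sum(sel)
      if (n == 0L) {
        med <- rep(NA_real_, length(targets)); pp <- rep(NA_real_, length(targets))
      } else {
        med <- vapply(targets, function(t) stats::median(corrected[[t]][sel]), numeric(1))
        pp <- 100 * colSums(positivity[sel, targets, drop = FALSE]) / n
      }
      per_sub[[s]] <- data.frame(patient_id = p, pc_subtype = s, target = targets,
                                 n_cells = n, median_level = unname(med),
                                 pct_positive = unname(pp),
                                 stringsAsFactors = FALSE)
    }
    block <- do.call(rbind, per_sub)
    if (!is.null(reference)) {
      ref <- per_sub[[reference]]
      if (ref$n_cells[1] == 0L) {
        abort_validation(paste0("patient ", p, " has no '", reference,
                                "' cells; reference normalisation undefined"))
      }
      i <- match(block$target, ref$target)
      block$rel_median_level <- block$median_level / ref$median_level[i]
      block$rel_pct_positive <- block$pct_positive / ref$pct_positive[i]
    }
    rows[[p]] <- block
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
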
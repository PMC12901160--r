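# Preprocessing: isotype background subtraction, positivity calling against
# the host-specific cut-offs, and exclusion of follicle-containing FOVs.

#' Subtract per-cell isotype background from every target
#'
#' For each cell and each non-control target, the intensity of the matching
#' isotype-control channel (same host class, same cell) is subtracted and
#' negative results are clamped to zero. The control columns are dropped from
#' the output; metadata columns are untouched. The returned table is marked
#' as corrected, and [call_positivity()] refuses a basis that does not match
#' the table's state.
#'
#' @param cells raw cell table (see [read_cell_table()]).
#' @param panel the matching `sscp_panel`.
#' @return cell table with background-corrected intensities.
#' @export
subtract_isotype_background <- function(cells, panel) {
  if (isTRUE(attr(cells, "isotype_subtracted"))) {
    abort_usage("cell table is already isotype-subtracted")
  }
  hosts <- target_hosts(panel)
  used_hosts <- unique(unname(hosts[gateable_targets(panel)]))
  ctrl <- vapply(used_hosts, function(h) isotype_channel(panel, h), character(1))
  miss <- setdiff(ctrl, names(cells))
  if (length(miss)) {
    abort_config(paste0("isotype-control column(s) missing from table: ",
                        paste(miss, collapse = ", ")))
  }
  for (t in gateable_targets(panel)) {
    cells[[t]] <- pmax(cells[[t]] - cells[[ctrl[[hosts[[t]]]]]], 0)
  }
  cells <- cells[, setdiff(names(cells), unname(ctrl)), drop = FALSE]
  attr(cells, "isotype_subtracted") <- TRUE
  cells
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a target when its intensity is at or above the
#' target's cut-off (30 for mouse IgG1-hosted, 100 for rabbit IgG-hosted
#' targets unless overridden per target; the boundary is inclusive). By
#' default positivity is computed on raw intensities; the corrected basis
#' applies the same cut-offs to background-subtracted values.
#'
#' @param cells cell table; its corrected/raw state must match `basis`.
#' @param panel the matching `sscp_panel`.
#' @param basis `"raw"` (default) or `"corrected"`.
#' @return logical matrix, cells x gateable targets, rownames = `cell_id`.
#' @export
call_positivity <- function(cells, panel, basis = c("raw", "corrected")) {
  basis <- match.arg(basis)
  subtracted <- isTRUE(attr(cells, "isotype_subtracted"))
  if (basis == "raw" && subtracted) {
    abort_usage("basis = 'raw' requires an uncorrected table, got an isotype-subtracted one")
  }
  if (basis == "corrected" && !subtracted) {
    abort_usage("basis = 'corrected' requires an isotype-subtracted table; run subtract_isotype_background() first")
  }
  cut <- target_cutoffs(panel)
  miss <- setdiff(names(cut), names(cells))
  if (length(miss)) {
    abort_format(paste0("cell table missing target column(s): ",
                        paste(miss, collapse = ", ")))
  }
  pos <- vapply(names(cut), function(t) cells[[t]] >= cut[[t]],
                logical(nrow(cells)))
  if (nrow(cells) == 1L) pos <- matrix(pos, nrow = 1, dimnames = list(NULL, names(cut)))
  rownames(pos) <- cells$cell_id
  pos
}

#' Exclude cells in follicle-containing FOVs
#'
#' Removes every cell whose FOV is flagged `contains_follicle`. The number of
#' excluded FOVs per patient is reported via `message()`; filtering an
#' already-filtered table is a no-op (idempotent).
#'
#' @param cells cell table.
#' @param fovs FOV annotations covering every `fov_id` in `cells`.
#' @return the filtered cell table (attributes preserved).
#' @export
filter_follicle_fovs <- function(cells, fovs) {
  fovs <- as_fov_annotations(fovs)
  i <- match(cells$fov_id, fovs$fov_id)
  if (anyNA(i)) {
    abort_validation(paste0("fov_id(s) absent from FOV annotations: ",
      paste(unique(cells$fov_id[is.na(i)]), collapse = ", ")))
  }
  drop <- fovs$contains_follicle[i]
  if (any(drop)) {
    excl <- unique(cells[drop, c("patient_id", "fov_id")])
    cnt <- table(excl$patient_id)
    message("follicle filter: excluded ",
            paste(sprintf("%s FOV(s) for patient %s", cnt, names(cnt)),
                  collapse = "; "))
  }
  out <- cells[!drop, , drop = FALSE]
  if (nrow(out) == 0L) {
    warning("all FOVs are follicle-flagged: no cells retained, downstream fractions are undefined")
  }
  attr(out, "isotype_subtracted") <- attr(cells, "isotype_subtracted")
  out
}
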
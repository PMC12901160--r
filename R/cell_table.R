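# Readers/writers and validation for the per-cell expression table and the
# FOV annotation table. Validation is total: any violated invariant raises a
# structured error naming the offending row/column; nothing is coerced
# silently.

#' Read field-of-view annotations
#'
#' One row per imaging field of view (FOV): `fov_id`, `patient_id`, the
#' lower-left corner of the FOV square in slide coordinates
#' (`origin_x_um`, `origin_y_um`), the follicle flag `contains_follicle`,
#' and optionally `side_um` (edge length; defaults to 500 um, i.e. the
#' 0.5 x 0.5 mm tile of the imager).
#'
#' @param path CSV/TSV file.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return data frame of annotations (possibly zero rows).
#' @export
read_fov_annotations <- function(path, sep = NULL) {
  df <- .read_delim(path, sep)
  as_fov_annotations(df)
}

#' Validate a FOV annotation data frame
#' @param df data frame with the columns described in [read_fov_annotations()].
#' @return the validated data frame.
#' @export
as_fov_annotations <- function(df) {
  need <- c("fov_id", "patient_id", "origin_x_um", "origin_y_um", "contains_follicle")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_format(paste0("FOV annotations missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  df$fov_id <- as.character(df$fov_id)
  df$patient_id <- as.character(df$patient_id)
  if (!"side_um" %in% names(df)) df$side_um <- rep(500, nrow(df))
  df$side_um[is.na(df$side_um)] <- 500
  df$side_um <- as.numeric(df$side_um)
  cf <- df$contains_follicle
  if (is.character(cf)) cf <- tolower(cf) %in% c("true", "t", "1", "yes")
  df$contains_follicle <- as.logical(cf)
  if (nrow(df) == 0L) return(df)
  if (anyNA(df$contains_follicle)) abort_format("contains_follicle must be logical")
  dup <- unique(df$fov_id[duplicated(df$fov_id)])
  if (length(dup)) {
    abort_validation(paste0("duplicate fov_id(s): ", paste(dup, collapse = ", ")))
  }
  if (any(!is.finite(df$side_um) | df$side_um <= 0)) {
    abort_validation("side_um must be positive and finite")
  }
  if (any(!is.finite(df$origin_x_um)) || any(!is.finite(df$origin_y_um))) {
    abort_validation("FOV origins must be finite")
  }
  df
}

#' Read a per-cell expression table
#'
#' The table has the fixed metadata columns `cell_id`, `patient_id`,
#' `condition`, `fov_id`, centroid coordinates `x_um`/`y_um` (micrometres,
#' global slide frame), optionally `area_um2`, plus exactly one raw-intensity
#' column per panel target. Row order is preserved.
#'
#' @param path CSV/TSV file.
#' @param panel the `sscp_panel` the columns must match.
#' @param fovs optional FOV annotations for cross-referencing `fov_id` and
#'   checking that each centroid lies in its declared FOV square (cells up to
#'   1 um outside are accepted with a warning; farther is an error).
#' @param condition_map optional named character vector mapping raw condition
#'   labels to `"case"`/`"control"` so the tool is not tied to one study's
#'   labels.
#' @param sep field separator; inferred from the extension when `NULL`.
#' @return validated cell table (data frame).
#' @export
read_cell_table <- function(path, panel, fovs = NULL, condition_map = NULL, sep = NULL) {
  df <- .read_delim(path, sep)
  validate_cell_table(df, panel, fovs = fovs, condition_map = condition_map)
}

#' Validate a cell table against a panel (and optionally FOV annotations)
#'
#' @inheritParams read_cell_table
#' @param cells data frame to validate.
#' @return the validated cell table.
#' @export
validate_cell_table <- function(cells, panel, fovs = NULL, condition_map = NULL) {
  meta_need <- setdiff(META_COLS, "area_um2")
  miss <- setdiff(meta_need, names(cells))
  if (length(miss)) {
    abort_format(paste0("cell table missing metadata column(s): ",
                        paste(miss, collapse = ", ")))
  }
  if (!"area_um2" %in% names(cells)) {
    warning("cell table has no area_um2 column; cell-size summaries will be skipped")
  }

  subtracted <- isTRUE(attr(cells, "isotype_subtracted"))
  expected <- if (subtracted) gateable_targets(panel) else panel$targets$name
  miss_t <- setdiff(expected, names(cells))
  if (length(miss_t)) {
    abort_format(paste0("cell table missing target column(s): ",
                        paste(miss_t, collapse = ", ")))
  }
  extra <- setdiff(names(cells), c(META_COLS, expected))
  if (length(extra)) {
    abort_validation(paste0("cell table has unknown column(s): ",
                            paste(extra, collapse = ", ")))
  }

  cells$cell_id <- as.character(cells$cell_id)
  cells$patient_id <- as.character(cells$patient_id)
  cells$condition <- as.character(cells$condition)
  cells$fov_id <- as.character(cells$fov_id)
  dup <- unique(cells$cell_id[duplicated(cells$cell_id)])
  if (length(dup)) {
    abort_validation(paste0("duplicate cell_id(s): ",
                            paste(utils::head(dup, 5), collapse = ", ")))
  }

  for (cc in intersect(c("x_um", "y_um", "area_um2"), names(cells))) {
    cells[[cc]] <- as.numeric(cells[[cc]])
    if (any(!is.finite(cells[[cc]]))) {
      abort_validation(paste0("non-finite values in column '", cc, "' (row ",
                              which(!is.finite(cells[[cc]]))[1], ")"))
    }
  }
  for (t in expected) {
    v <- suppressWarnings(as.numeric(cells[[t]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort_validation(sprintf(
        "intensity column '%s' has negative or non-finite value at row %d", t, bad[1]))
    }
    cells[[t]] <- v
  }

  if (!is.null(condition_map)) {
    unmapped <- setdiff(unique(cells$condition), names(condition_map))
    if (length(unmapped)) {
      abort_validation(paste0("condition label(s) not in condition_map: ",
                              paste(unmapped, collapse = ", ")))
    }
    cells$condition <- unname(condition_map[cells$condition])
  }

  if (!is.null(fovs)) {
    fovs <- as_fov_annotations(fovs)
    missing_fov <- setdiff(unique(cells$fov_id), fovs$fov_id)
    if (length(missing_fov)) {
      abort_validation(paste0("fov_id(s) absent from FOV annotations: ",
                              paste(missing_fov, collapse = ", ")))
    }
    i <- match(cells$fov_id, fovs$fov_id)
    ox <- fovs$origin_x_um[i]; oy <- fovs$origin_y_um[i]; side <- fovs$side_um[i]
    excess <- pmax(ox - cells$x_um, cells$x_um - (ox + side),
                   oy - cells$y_um, cells$y_um - (oy + side), 0)
    if (any(excess > 1)) {
      abort_validation(sprintf(
        "cell '%s' lies %.2f um outside its declared FOV square",
        cells$cell_id[which.max(excess)], max(excess)))
    }
    if (any(excess > 0)) {
      warning(sprintf("%d cell(s) lie within 1 um outside their FOV square; accepted",
                      sum(excess > 0)))
    }
  }

  cells
}

#' Write a cell table (round-trip safe)
#'
#' Numeric columns are written with 17 significant digits so that reading the
#' file back reproduces every double bit-identically.
#'
#' @param cells cell table.
#' @param path output CSV path.
#' @export
write_cell_table <- function(cells, path) {
  .write_table(cells, path)
}

#' Write FOV annotations to CSV
#' @param fovs FOV annotation data frame.
#' @param path output CSV path.
#' @export
write_fov_annotations <- function(fovs, path) {
  .write_table(fovs, path)
}
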
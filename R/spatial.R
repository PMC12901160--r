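# Spatial statistics: nearest-epithelium distances per PC, per-subtype median
# distances, Vim+ LP cell density per mm^2, and cell-size summaries.

# O(n^2) scan, chunked over queries to bound memory. Kept as the reference
# backend the accelerated k-d tree must agree with.
.nn_min_dist_brute <- function(ax, ay, qx, qy, chunk = 512L) {
  if (length(ax) == 0L) abort_validation("no anchor points")
  out <- numeric(length(qx))
  for (s in seq(1L, length(qx), by = chunk)) {
    e <- min(s + chunk - 1L, length(qx))
    dx <- outer(qx[s:e], ax, "-")
    dy <- outer(qy[s:e], ay, "-")
    out[s:e] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

.nn_min_dist <- function(ax, ay, qx, qy, method = c("kdtree", "brute")) {
  method <- match.arg(method)
  if (length(qx) == 0L) return(numeric(0))
  if (method == "kdtree") .nn_min_dist_kd(ax, ay, qx, qy)
  else .nn_min_dist_brute(ax, ay, qx, qy)
}

#' Distance of every plasma cell to the nearest epithelial cell
#'
#' For each PC, the Euclidean centroid distance (um) to the nearest
#' epithelium-marker-positive cell of the same patient. By default distances
#' are computed on the stitched slide coordinates across all of the patient's
#' FOVs (tissue is contiguous); `within_fov = TRUE` restricts anchors to the
#' query cell's own FOV. Anchor cells may come from a separate, unfiltered
#' table (`anchors`/`anchor_positivity`) so that epithelial cells in
#' follicle-flagged FOVs still define the tissue geometry.
#'
#' @param cells cell table holding the query cells.
#' @param positivity positivity matrix aligned with `cells`.
#' @param labels output of [classify_cells()] aligned with `cells`; rows with
#'   `lineage == "PC"` are the queries.
#' @param anchors,anchor_positivity optional cell table + positivity matrix
#'   supplying the epithelial anchors; default to `cells`/`positivity`.
#' @param epithelium_marker positivity column defining epithelium
#'   (default `"EpCAM"`).
#' @param method `"kdtree"` (accelerated, default) or `"brute"` (exhaustive
#'   scan); both return identical distances.
#' @param within_fov restrict anchors to the query's FOV.
#' @return data frame: `cell_id`, `patient_id`, `fov_id`, `pc_subtype`,
#'   `distance_um` (`NA`, with a warning, for patients without any anchor).
#' @export
nearest_epithelium_distance <- function(cells, positivity, labels,
                                        anchors = NULL, anchor_positivity = NULL,
                                        epithelium_marker = "EpCAM",
                                        method = c("kdtree", "brute"),
                                        within_fov = FALSE) {
  method <- match.arg(method)
  stopifnot(nrow(cells) == nrow(positivity), nrow(cells) == nrow(labels))
  anchors <- anchors %||% cells
  anchor_positivity <- anchor_positivity %||% positivity
  stopifnot(nrow(anchors) == nrow(anchor_positivity))
  if (!epithelium_marker %in% colnames(anchor_positivity)) {
    abort_config(paste0("positivity matrix has no '", epithelium_marker, "' column"))
  }

  is_q <- labels$lineage == "PC"
  is_a <- anchor_positivity[, epithelium_marker]
  q <- cells[is_q, c("cell_id", "patient_id", "fov_id", "x_um", "y_um")]
  q$pc_subtype <- as.character(labels$pc_subtype[is_q])
  q$distance_um <- NA_real_

  for (p in unique(q$patient_id)) {
    ai <- is_a & anchors$patient_id == p
    qi <- which(q$patient_id == p)
    if (!any(ai)) {
      warning(paste0("patient ", p, " has no ", epithelium_marker,
                     "+ cells; distances undefined"))
      next
    }
    if (within_fov) {
      for (f in unique(q$fov_id[qi])) {
        aif <- ai & anchors$fov_id == f
        qif <- qi[q$fov_id[qi] == f]
        if (!any(aif)) {
          warning(paste0("FOV ", f, " has no ", epithelium_marker, "+ cells"))
          next
        }
        q$distance_um[qif] <- .nn_min_dist(anchors$x_um[aif], anchors$y_um[aif],
                                           q$x_um[qif], q$y_um[qif], method)
      }
    } else {
      q$distance_um[qi] <- .nn_min_dist(anchors$x_um[ai], anchors$y_um[ai],
                                        q$x_um[qi], q$y_um[qi], method)
    }
  }
  rownames(q) <- NULL
  q[, c("cell_id", "patient_id", "fov_id", "pc_subtype", "distance_um")]
}

#' Median nearest-epithelium distance per patient and PC subtype
#'
#' @param records output of [nearest_epithelium_distance()].
#' @return data frame: `patient_id`, `pc_subtype`, `n`, `median_distance_um`
#'   (rows only for non-empty groups).
#' @export
median_distance_per_subtype <- function(records) {
  recs <- records[!is.na(records$distance_um), , drop = FALSE]
  if (nrow(recs) == 0L) {
    return(data.frame(patient_id = character(0), pc_subtype = character(0),
                      n = integer(0), median_distance_um = numeric(0)))
  }
  agg <- aggregate(distance_um ~ patient_id + pc_subtype, data = recs,
                   FUN = stats::median)
  cnt <- aggregate(distance_um ~ patient_id + pc_subtype, data = recs,
                   FUN = length)
  names(agg)[3] <- "median_distance_um"
  agg$n <- cnt$distance_um[match(paste(agg$patient_id, agg$pc_subtype),
                                 paste(cnt$patient_id, cnt$pc_subtype))]
  agg[order(agg$patient_id, match(agg$pc_subtype, PC_SUBTYPES)),
      c("patient_id", "pc_subtype", "n", "median_distance_um")]
}

#' Vim+ LP cell density per mm^2 of analysed tissue
#'
#' Tissue area is approximated by the summed area of the patient's retained
#' (non-follicle) FOVs; no tissue mask is attempted. `cells`/`labels` are
#' expected to be follicle-filtered already.
#'
#' @param cells follicle-filtered cell table.
#' @param fovs FOV annotations (all FOVs, flags included).
#' @param labels output of [classify_cells()] aligned with `cells`.
#' @return data frame: `patient_id`, `n_vim`, `n_fovs`, `area_mm2`,
#'   `density_per_mm2` (`NA` with a warning when a patient has no retained FOV).
#' @export
lp_cell_density <- function(cells, fovs, labels) {
  stopifnot(nrow(cells) == nrow(labels))
  fovs <- as_fov_annotations(fovs)
  vim <- .is_vim_lp(labels)
  pats <- unique(fovs$patient_id)
  out <- data.frame(patient_id = pats, n_vim = NA_integer_, n_fovs = NA_integer_,
                    area_mm2 = NA_real_, density_per_mm2 = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(pats)) {
    keep <- fovs$patient_id == pats[k] & !fovs$contains_follicle
    out$n_fovs[k] <- sum(keep)
    out$n_vim[k] <- sum(vim & cells$patient_id == pats[k])
    if (!any(keep)) {
      warning(paste0("patient ", pats[k], " has no retained FOVs; density undefined"))
      next
    }
    out$area_mm2[k] <- sum((fovs$side_um[keep] / 1000)^2)
    out$density_per_mm2[k] <- out$n_vim[k] / out$area_mm2[k]
  }
  out
}

#' Median cell area per patient and PC subtype
#'
#' Skipped (returns `NULL` with a warning) when the table has no `area_um2`
#' column, which is an optional input.
#'
#' @param cells cell table.
#' @param labels output of [classify_cells()] aligned with `cells`.
#' @return data frame `patient_id`, `pc_subtype`, `n`, `median_area_um2`,
#'   or `NULL`.
#' @export
cell_size_summary <- function(cells, labels) {
  stopifnot(nrow(cells) == nrow(labels))
  if (!"area_um2" %in% names(cells)) {
    warning("no area_um2 column: cell-size summary skipped")
    return(NULL)
  }
  sel <- labels$lineage == "PC"
  if (!any(sel)) {
    return(data.frame(patient_id = character(0), pc_subtype = character(0),
                      n = integer(0), median_area_um2 = numeric(0)))
  }
  d <- data.frame(patient_id = cells$patient_id[sel],
                  pc_subtype = as.character(labels$pc_subtype[sel]),
                  area = cells$area_um2[sel], stringsAsFactors = FALSE)
  agg <- aggregate(area ~ patient_id + pc_subtype, data = d, FUN = stats::median)
  cnt <- aggregate(area ~ patient_id + pc_subtype, data = d, FUN = length)
  names(agg)[3] <- "median_area_um2"
  agg$n <- cnt$area[match(paste(agg$patient_id, agg$pc_subtype),
                          paste(cnt$patient_id, cnt$pc_subtype))]
  agg[order(agg$patient_id, match(agg$pc_subtype, PC_SUBTYPES)),
      c("patient_id", "pc_subtype", "n", "median_area_um2")]
}
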
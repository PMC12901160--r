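# Panel definition: the multiplexed target list, each target's host isotype
# class and positivity cut-off, and the isotype-control channels used for
# background estimation.

#' Host-specific default positivity cut-offs
#'
#' Positivity cut-offs in raw fluorescence units, keyed by the host isotype
#' class of the staining antibody: 30 for mouse IgG1-hosted targets, 100 for
#' rabbit IgG-hosted targets. Per-target overrides can be supplied in the
#' panel file via an optional `cutoff` column.
#' @export
HOST_CUTOFFS <- c(mouse_IgG1 = 30, rabbit_IgG = 100)

#' Construct a panel from a data frame
#'
#' A panel has one row per channel with columns `name`, `host`
#' (`"mouse_IgG1"` or `"rabbit_IgG"`), logical `is_isotype_control`, and an
#' optional numeric `cutoff`. Missing cut-offs are filled from
#' [HOST_CUTOFFS]; isotype-control channels never carry a cut-off and are
#' excluded from gating. Exactly one control channel per host class must be
#' present, so every target has a background channel.
#'
#' @param df data frame with the columns above.
#' @return An object of class `sscp_panel`.
#' @export
as_panel <- function(df) {
  need <- c("name", "host", "is_isotype_control")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_format(paste0("panel is missing required column(s): ",
                        paste(miss, collapse = ", ")))
  }
  df$name <- as.character(df$name)
  df$host <- as.character(df$host)
  ctl <- df$is_isotype_control
  if (is.character(ctl)) ctl <- tolower(ctl) %in% c("true", "t", "1", "yes")
  df$is_isotype_control <- as.logical(ctl)
  if (anyNA(df$is_isotype_control)) {
    abort_format("is_isotype_control must be logical (true/false)")
  }

  bad_host <- setdiff(unique(df$host), names(HOST_CUTOFFS))
  if (length(bad_host)) {
    abort_validation(paste0("unknown host class(es): ",
                            paste(bad_host, collapse = ", "),
                            " (expected ", paste(names(HOST_CUTOFFS), collapse = " or "), ")"))
  }
  dup <- unique(df$name[duplicated(df$name)])
  if (length(dup)) {
    abort_validation(paste0("duplicate target name(s) in panel: ",
                            paste(dup, collapse = ", ")))
  }

  if (!"cutoff" %in% names(df)) df$cutoff <- NA_real_
  df$cutoff <- suppressWarnings(as.numeric(df$cutoff))
  fill <- !df$is_isotype_control & is.na(df$cutoff)
  df$cutoff[fill] <- unname(HOST_CUTOFFS[df$host[fill]])
  df$cutoff[df$is_isotype_control] <- NA_real_
  if (any(df$cutoff < 0, na.rm = TRUE)) {
    abort_validation("positivity cut-offs must be nonnegative")
  }

  for (h in unique(df$host)) {
    nctl <- sum(df$is_isotype_control & df$host == h)
    if (nctl != 1L) {
      abort_validation(sprintf(
        "host class '%s' must have exactly one isotype-control channel (found %d)",
        h, nctl))
    }
  }

  structure(list(targets = df[, c("name", "host", "is_isotype_control", "cutoff")]),
            class = "sscp_panel")
}

#' Read a panel definition table
#'
#' @param path CSV/TSV file with columns `name`, `host`,
#'   `is_isotype_control` and optionally `cutoff`.
#' @param sep field separator; inferred from the file extension when `NULL`.
#' @return An `sscp_panel`.
#' @seealso [as_panel()], [default_panel()]
#' @export
read_panel <- function(path, sep = NULL) {
  as_panel(.read_delim(path, sep))
}

#' @export
print.sscp_panel <- function(x, ...) {
  tg <- x$targets
  cat(sprintf("<sscp_panel> %d channels: %d gateable targets, %d isotype controls\n",
              nrow(tg), sum(!tg$is_isotype_control), sum(tg$is_isotype_control)))
  for (h in unique(tg$host)) {
    cat(sprintf("  %s: %d targets (cutoff %g), control channel '%s'\n",
                h, sum(!tg$is_isotype_control & tg$host == h),
                HOST_CUTOFFS[[h]], isotype_channel(x, h)))
  }
  invisible(x)
}

#' Gateable (non-control) target names of a panel, in panel order
#' @param panel an `sscp_panel`.
#' @export
gateable_targets <- function(panel) {
  panel$targets$name[!panel$targets$is_isotype_control]
}

#' Isotype-control channel name for a host class
#' @param panel an `sscp_panel`.
#' @param host host class, e.g. `"mouse_IgG1"`.
#' @export
isotype_channel <- function(panel, host) {
  tg <- panel$targets
  hit <- tg$name[tg$is_isotype_control & tg$host == host]
  if (length(hit) != 1L) {
    abort_config(paste0("no isotype-control channel for host class '", host, "'"))
  }
  hit
}

# Named cutoff / host lookups over gateable targets.
target_cutoffs <- function(panel) {
  tg <- panel$targets[!panel$targets$is_isotype_control, ]
  stats::setNames(tg$cutoff, tg$name)
}

target_hosts <- function(panel) {
  tg <- panel$targets
  stats::setNames(tg$host, tg$name)
}

#' Default target exclusion list for plasma-cell phenotyping
#'
#' Thirteen targets unrelated to the B-cell compartment that are dropped
#' before PC-level phenotyping (continuous summaries and embeddings):
#' Beta-catenin, CD16, CD3, CD4, CD56, CD68, CD8, EGFR, EpCAM, Fibronectin,
#' FOXP3, Her2 and SMA.
#' @return character vector of 13 target names.
#' @export
default_pc_exclusions <- function() {
  c("Beta-catenin", "CD16", "CD3", "CD4", "CD56", "CD68", "CD8",
    "EGFR", "EpCAM", "Fibronectin", "FOXP3", "Her2", "SMA")
}

#' Restrict a panel to phenotyping targets
#'
#' Drops the isotype controls plus an exclusion list of targets irrelevant to
#' the population being phenotyped (defaults to the 13-name B-cell-unrelated
#' set, [default_pc_exclusions()]).
#'
#' @param panel an `sscp_panel`.
#' @param exclusions character vector of target names to drop; every name
#'   must exist in the panel (misspellings are errors, not silently ignored).
#' @return character vector of retained target names, in panel order.
#' @export
select_phenotyping_targets <- function(panel, exclusions = default_pc_exclusions()) {
  all_t <- gateable_targets(panel)
  unknown <- setdiff(exclusions, panel$targets$name)
  if (length(unknown)) {
    abort_config(paste0("exclusion name(s) not in panel: ",
                        paste(unknown, collapse = ", ")))
  }
  setdiff(all_t, exclusions)
}

#' Built-in 64-plex panel
#'
#' A synthetic default panel emulating a commercial 64-plex immuno-oncology
#' protein panel: 62 gateable targets plus one isotype-control channel per
#' host class (`Ms IgG1`, `Rb IgG`). Target names cover the full gating
#' vocabulary used by [default_gates()] and the 13-name exclusion list; the
#' list is a stand-in written for this package, not a vendor export.
#'
#' @return An `sscp_panel` with 64 rows.
#' @export
default_panel <- function() {
  rabbit <- c("EGFR", "Her2", "Beta-catenin", "Fibronectin", "SMA",
              "NF-kB p65", "pan-RAS", "STING", "IDO1", "iNOS")
  targets <- c(
    "CD19", "CD20", "CD21", "CD27", "CD38", "CD45", "CD45RO", "CD138",
    "Ki-67", "Vimentin", "PanCK", "EpCAM", "B2M", "CD298",
    "CD3", "CD4", "CD8", "CD11c", "CD14", "CD16", "CD56", "CD68", "CD163",
    "HLA-DR", "IgD", "CD40", "CD44", "CD31", "CD34", "CD127", "CD25",
    "FOXP3", "CTLA4", "PD-1", "PD-L1", "PD-L2", "LAG3", "Tim-3", "VISTA",
    "ICOS", "OX40L", "GITR", "4-1BB", "B7-H3", "STING", "IDO1", "iNOS",
    "Granzyme B", "EGFR", "Her2", "Beta-catenin", "Fibronectin", "SMA",
    "NF-kB p65", "pan-RAS", "Bcl-2", "CD15", "CD30", "CD57", "CD66b",
    "CD39", "TCF7")
  stopifnot(length(targets) == 62L, !anyDuplicated(targets))
  df <- data.frame(
    name = c(targets, "Ms IgG1", "Rb IgG"),
    host = c(ifelse(targets %in% rabbit, "rabbit_IgG", "mouse_IgG1"),
             "mouse_IgG1", "rabbit_IgG"),
    is_isotype_control = c(rep(FALSE, 62L), TRUE, TRUE),
    stringsAsFactors = FALSE)
  as_panel(df)
}

#' Write a panel definition to CSV
#' @param panel an `sscp_panel`.
#' @param path output file.
#' @export
write_panel <- function(panel, path) {
  .write_table(panel$targets, path)
}
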
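# End-to-end orchestration: read (or simulate) -> subtract/positivity ->
# follicle filter -> classify -> fractions/abundance/summaries -> spatial ->
# cohort statistics, with CSV artifacts and a resolved-config record.

#' Build a pipeline configuration
#'
#' `x` is a named list or the path to a YAML file with the same layout.
#' Recognised fields (all optional unless noted):
#' * `input`: directory holding `cells.csv`, `panel.csv`, `fovs.csv`
#'   (single-file container), or a list with explicit `cells`/`panel`/`fovs`
#'   paths — required unless `simulate` is given;
#' * `simulate`: list of [synthetic_spec()] arguments to run on simulated
#'   data instead;
#' * `positivity_basis`: `"raw"` (default) or `"corrected"`;
#' * `follicle_filter`: logical, default `TRUE` (applied to all stages);
#' * `gates`: path to a YAML gate library (default: [default_gates()]);
#' * `exclusions`: targets dropped for PC-level summaries
#'   (default [default_pc_exclusions()]);
#' * `condition_map`: named map raw label -> `"case"`/`"control"`;
#' * `reference_subtype`: subtype for relative marker summaries, default
#'   `"CD19+CD45+"`;
#' * `case`, `control`: which condition labels form each comparison group
#'   (defaults `"case"`/`"control"`);
#' * `out_dir`: where to write report CSVs (omit to keep results in memory);
#' * `seed`: integer, drives the simulation.
#'
#' @param x list or YAML path.
#' @return validated config of class `sscp_config`.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) x <- yaml::read_yaml(x)
  if (!is.list(x)) abort_config("config must be a list or a YAML file path")
  defaults <- list(
    input = NULL, simulate = NULL,
    positivity_basis = "raw", follicle_filter = TRUE,
    gates = NULL, exclusions = default_pc_exclusions(),
    condition_map = NULL, reference_subtype = "CD19+CD45+",
    case = "case", control = "control",
    epithelium_marker = "EpCAM", distance_within_fov = FALSE,
    out_dir = NULL, seed = 1L)
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown)) {
    abort_config(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  if (!cfg$positivity_basis %in% c("raw", "corrected")) {
    abort_config("positivity_basis must be 'raw' or 'corrected'")
  }
  if (is.null(cfg$input) && is.null(cfg$simulate)) {
    abort_config("config needs either 'input' paths or a 'simulate' spec")
  }
  class(cfg) <- "sscp_config"
  cfg
}

.load_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    args <- cfg$simulate
    args$seed <- args$seed %||% cfg$seed
    spec <- do.call(synthetic_spec, args)
    sim <- generate_cohort(spec)
    return(list(cells = sim$cells, fovs = sim$fovs, panel = sim$panel,
                truth = sim$truth))
  }
  inp <- cfg$input
  if (is.character(inp)) {
    inp <- list(cells = file.path(inp, "cells.csv"),
                panel = file.path(inp, "panel.csv"),
                fovs = file.path(inp, "fovs.csv"))
  }
  panel <- read_panel(inp$panel)
  fovs <- read_fov_annotations(inp$fovs)
  cells <- read_cell_table(inp$cells, panel, fovs = fovs,
                           condition_map = cfg$condition_map)
  list(cells = cells, fovs = fovs, panel = panel, truth = NULL)
}

.patient_conditions <- function(cells) {
  u <- unique(cells[, c("patient_id", "condition")])
  stats::setNames(u$condition, u$patient_id)
}

# Case-vs-control Mann-Whitney over a per-patient statistic.
.compare <- function(label, values, patients, cond_of, case, control) {
  g <- cond_of[patients]
  xs <- values[g == case & !is.na(values)]
  ys <- values[g == control & !is.na(values)]
  if (length(xs) == 0L || length(ys) == 0L) {
    return(data.frame(comparison = label, n_case = length(xs),
                      n_control = length(ys), median_case = NA_real_,
                      median_control = NA_real_, U = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE))
  }
  mw <- mann_whitney(xs, ys)
  data.frame(comparison = label, n_case = mw$n_x, n_control = mw$n_y,
             median_case = stats::median(xs), median_control = stats::median(ys),
             U = mw$statistic, p = mw$p_value, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on real or simulated input and returns (and
#' optionally writes) the report bundle: per-patient summaries, case/control
#' comparisons (unadjusted and Holm-Sidak-adjusted p values are both
#' reported), per-subtype distance medians, densities, cell sizes, and the
#' resolved configuration for provenance. Outputs are deterministic given the
#' config and seed.
#'
#' @param config an `sscp_config`, a list, or a YAML path
#'   (see [pipeline_config()]).
#' @return invisibly, a list with `cells`, `positivity`, `labels`,
#'   `marker_fractions`, `pc_fractions`, `abundance`, `marker_summary`,
#'   `distances`, `distance_medians`, `density`, `cell_sizes`,
#'   `comparisons`, `panel`, `config` (and `truth` when simulated).
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "sscp_config")) config else pipeline_config(config)
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  inp <- .load_inputs(cfg)
  raw <- inp$cells
  fovs <- inp$fovs
  panel <- inp$panel
  say("input: %d cells, %d FOVs, %d patients", nrow(raw), nrow(fovs),
      length(unique(raw$patient_id)))

  gates <- if (is.null(cfg$gates)) default_gates() else read_gate_library(cfg$gates)
  for (g in gates) {
    bad <- setdiff(names(g), gateable_targets(panel))
    if (length(bad)) {
      abort_config(paste0("gate references target(s) not in panel: ",
                          paste(bad, collapse = ", ")))
    }
  }
  pheno_targets <- select_phenotyping_targets(panel, cfg$exclusions)

  # positivity on the full table first: epithelial distance anchors are exempt
  # from the follicle filter (they define tissue geometry)
  pos_all <- call_positivity(raw, panel, basis = "raw")

  cells <- if (isTRUE(cfg$follicle_filter)) filter_follicle_fovs(raw, fovs) else raw
  truth <- inp$truth
  if (!is.null(truth)) truth <- truth[match(cells$cell_id, truth$cell_id), ]
  say("follicle filter %s: %d cells retained",
      if (isTRUE(cfg$follicle_filter)) "on" else "off", nrow(cells))

  corrected <- subtract_isotype_background(cells, panel)
  positivity <- if (cfg$positivity_basis == "raw") {
    call_positivity(cells, panel, basis = "raw")
  } else {
    call_positivity(corrected, panel, basis = "corrected")
  }
  labels <- classify_cells(positivity, gates)
  say("labels: %d LP immune, %d PB, %d PC, %d non-LP",
      sum(labels$lineage == "LP_immune"), sum(labels$lineage == "PB"),
      sum(labels$lineage == "PC"), sum(labels$lineage == "non_LP"))

  mfrac <- marker_fractions(cells, positivity, labels)
  pcfrac <- pc_subtype_fractions(cells, labels)
  msum <- subtype_marker_summary(corrected, positivity, labels,
                                 targets = pheno_targets,
                                 reference = NULL)

  dist <- nearest_epithelium_distance(cells, positivity, labels,
                                      anchors = raw, anchor_positivity = pos_all,
                                      epithelium_marker = cfg$epithelium_marker,
                                      within_fov = isTRUE(cfg$distance_within_fov))
  dmed <- median_distance_per_subtype(dist)
  dens <- lp_cell_density(cells, fovs, labels)
  sizes <- cell_size_summary(cells, labels)

  # per-patient B-lineage abundance (% of Vim+ LP cells) and its relative form
  cond_of <- .patient_conditions(cells)
  pats <- names(cond_of)
  vim <- .is_vim_lp(labels)
  pb_pct <- pc_pct <- stats::setNames(rep(NA_real_, length(pats)), pats)
  for (p in pats) {
    sel <- cells$patient_id == p & vim
    if (any(sel)) {
      pb_pct[p] <- 100 * sum(labels$lineage[sel] == "PB") / sum(sel)
      pc_pct[p] <- 100 * sum(labels$lineage[sel] == "PC") / sum(sel)
    }
  }
  is_ctl <- cond_of == cfg$control
  abundance <- data.frame(patient_id = pats, condition = unname(cond_of),
                          pb_pct = unname(pb_pct), pc_pct = unname(pc_pct),
                          stringsAsFactors = FALSE)
  if (any(is_ctl)) {
    for (col in c("pb_pct", "pc_pct")) {
      ra <- tryCatch(
        relative_abundance(abundance[[col]][!is_ctl], abundance[[col]][is_ctl]),
        sscp_error = function(e) NULL)
      rel <- rep(NA_real_, nrow(abundance))
      if (!is.null(ra)) { rel[!is_ctl] <- ra$case; rel[is_ctl] <- ra$control }
      abundance[[sub("pct", "rel", col)]] <- rel
    }
  }

  # cohort comparisons
  cmp <- list()
  for (s in PC_SUBTYPES) {
    v <- stats::setNames(pcfrac$pct[pcfrac$pc_subtype == s],
                         pcfrac$patient_id[pcfrac$pc_subtype == s])
    cmp[[length(cmp) + 1L]] <- .compare(paste0("pc_fraction ", s), v, names(v),
                                        cond_of, cfg$case, cfg$control)
  }
  for (t in intersect(c("CD19", "CD20", "CD27", "CD38", "CD138", "Ki-67"),
                      colnames(positivity))) {
    v <- stats::setNames(mfrac$pct[mfrac$target == t],
                         mfrac$patient_id[mfrac$target == t])
    cmp[[length(cmp) + 1L]] <- .compare(paste0("marker_fraction ", t), v,
                                        names(v), cond_of, cfg$case, cfg$control)
  }
  for (col in c("pb_pct", "pc_pct")) {
    v <- stats::setNames(abundance[[col]], abundance$patient_id)
    cmp[[length(cmp) + 1L]] <- .compare(paste0("abundance ", col), v, names(v),
                                        cond_of, cfg$case, cfg$control)
  }
  v <- stats::setNames(dens$density_per_mm2, dens$patient_id)
  cmp[[length(cmp) + 1L]] <- .compare("vim_lp_density_per_mm2", v, names(v),
                                      cond_of, cfg$case, cfg$control)
  comparisons <- do.call(rbind, cmp)
  ok <- !is.na(comparisons$p)
  comparisons$p_holm_sidak <- NA_real_
  comparisons$p_holm_sidak[ok] <- adjust_pvalues(comparisons$p[ok], "holm_sidak")
  say("comparisons: %d tests (%d significant at unadjusted p <= 0.05)",
      sum(ok), sum(comparisons$p[ok] <= 0.05))

  res <- list(cells = cells, positivity = positivity, labels = labels,
              marker_fractions = mfrac, pc_fractions = pcfrac,
              abundance = abundance, marker_summary = msum,
              distances = dist, distance_medians = dmed, density = dens,
              cell_sizes = sizes, comparisons = comparisons,
              panel = panel, config = cfg, truth = truth)

  if (!is.null(cfg$out_dir)) {
    d <- cfg$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    .write_table(mfrac, file.path(d, "marker_fractions.csv"))
    .write_table(pcfrac, file.path(d, "pc_subtype_fractions.csv"))
    .write_table(abundance, file.path(d, "abundance.csv"))
    .write_table(msum, file.path(d, "subtype_marker_summary.csv"))
    .write_table(dmed, file.path(d, "distance_medians.csv"))
    .write_table(dens, file.path(d, "density.csv"))
    if (!is.null(sizes)) .write_table(sizes, file.path(d, "cell_sizes.csv"))
    .write_table(comparisons, file.path(d, "comparisons.csv"))
    cfg_out <- unclass(cfg)
    cfg_out$exclusions <- as.list(cfg_out$exclusions)
    yaml::write_yaml(cfg_out, file.path(d, "resolved_config.yaml"))
    writeLines(log_lines, file.path(d, "run_log.txt"))
    say("report written to %s", d)
  }
  invisible(res)
}
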
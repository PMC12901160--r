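# Small in-code fixtures and independent oracles shared across test files.

tiny_panel <- function() {
  as_panel(data.frame(
    name = c("Vimentin", "CD138", "CD19", "CD45", "CD20", "CD27", "CD38",
             "EpCAM", "NF-kB p65", "Ms IgG1", "Rb IgG"),
    host = c(rep("mouse_IgG1", 8), "rabbit_IgG", "mouse_IgG1", "rabbit_IgG"),
    is_isotype_control = c(rep(FALSE, 9), TRUE, TRUE),
    stringsAsFactors = FALSE))
}

tiny_cells <- function(panel = tiny_panel(), n = 10, patient = "P1",
                       fov = "F1", seed = 1) {
  set.seed(seed)
  df <- data.frame(cell_id = sprintf("%s_c%03d", patient, seq_len(n)),
                   patient_id = patient, condition = "case", fov_id = fov,
                   x_um = runif(n, 0, 500), y_um = runif(n, 0, 500),
                   area_um2 = runif(n, 50, 150),
                   stringsAsFactors = FALSE, check.names = FALSE)
  for (t in panel$targets$name) df[[t]] <- round(runif(n, 0, 200), 3)
  df
}

tiny_fovs <- function(fov_ids = "F1", patient = "P1", follicle = FALSE) {
  data.frame(fov_id = fov_ids, patient_id = patient,
             origin_x_um = 0, origin_y_um = 0, side_um = 500,
             contains_follicle = follicle, stringsAsFactors = FALSE)
}

# random positivity matrix over the tiny panel's gateable targets
random_positivity <- function(n, p = 0.5, targets = gateable_targets(tiny_panel())) {
  m <- matrix(runif(n * length(targets)) < p, n, length(targets),
              dimnames = list(NULL, targets))
  m
}

# Plain per-cell if/else restatement of the phenotyping hierarchy,
# independent of the gate machinery.
oracle_classify <- function(pos) {
  n <- nrow(pos)
  lineage <- character(n); subtype <- character(n)
  for (i in seq_len(n)) {
    r <- pos[i, ]
    if (r[["Vimentin"]] && r[["CD138"]]) {
      lineage[i] <- "PC"
      subtype[i] <-
        if (r[["CD19"]] && r[["CD45"]]) "CD19+CD45+"
        else if (!r[["CD19"]] && r[["CD45"]]) "CD19-CD45+"
        else if (!r[["CD19"]] && !r[["CD45"]]) "CD19-CD45-"
        else "other"
    } else if (r[["Vimentin"]] && r[["CD19"]] && r[["CD27"]] && r[["CD38"]] &&
               !r[["CD20"]] && !r[["CD138"]]) {
      lineage[i] <- "PB"; subtype[i] <- "not_a_PC"
    } else if (r[["Vimentin"]]) {
      lineage[i] <- "LP_immune"; subtype[i] <- "not_a_PC"
    } else {
      lineage[i] <- "non_LP"; subtype[i] <- "not_a_PC"
    }
  }
  data.frame(lineage = lineage, pc_subtype = subtype, stringsAsFactors = FALSE)
}

# Exact two-sided Mann-Whitney p by full enumeration over all C(n, n_x)
# label assignments of the pooled sample (tie-free null is symmetric around
# n_x n_y / 2, so the two-sided p is the symmetric tail mass).
mw_u <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))

mw_exact_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  u_obs <- mw_u(x, y)
  mu <- nx * length(y) / 2
  combs <- utils::combn(length(pool), nx)
  u_all <- apply(combs, 2, function(idx) mw_u(pool[idx], pool[-idx]))
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}
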
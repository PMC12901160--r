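test_that("gate evaluation matches the plasmablast definition", {
  pb <- default_gates()$PB
  row <- c(Vimentin = TRUE, CD138 = FALSE, CD19 = TRUE, CD45 = TRUE,
           CD20 = FALSE, CD27 = TRUE, CD38 = TRUE, EpCAM = FALSE,
           `NF-kB p65` = FALSE)
  expect_true(evaluate_gate(row, pb))
  row["CD138"] <- TRUE
  expect_false(evaluate_gate(row, pb))

  expect_warning(v <- evaluate_gate(row, character(0)), "vacuous")
  expect_true(v)
  expect_error(evaluate_gate(row, c(CD99 = "+")), class = "sscp_config_error")
})

test_that("classification follows the marker hierarchy", {
  mk <- function(...) {
    base <- c(Vimentin = FALSE, CD138 = FALSE, CD19 = FALSE, CD45 = FALSE,
              CD20 = FALSE, CD27 = FALSE, CD38 = FALSE, EpCAM = FALSE,
              `NF-kB p65` = FALSE)
    base[names(c(...))] <- c(...)
    base
  }
  pos <- rbind(mk(Vimentin = TRUE, CD138 = TRUE, CD19 = TRUE, CD45 = TRUE),
               mk(Vimentin = TRUE, CD138 = TRUE, CD45 = TRUE),
               mk(Vimentin = TRUE, CD138 = TRUE),
               mk(Vimentin = TRUE, CD138 = TRUE, CD19 = TRUE),
               mk(Vimentin = TRUE, CD19 = TRUE, CD27 = TRUE, CD38 = TRUE),
               mk(Vimentin = TRUE, CD45 = TRUE),
               mk(EpCAM = TRUE, CD138 = TRUE, CD19 = TRUE))
  lab <- classify_cells(pos)
  expect_equal(as.character(lab$lineage),
               c("PC", "PC", "PC", "PC", "PB", "LP_immune", "non_LP"))
  expect_equal(as.character(lab$pc_subtype),
               c("CD19+CD45+", "CD19-CD45+", "CD19-CD45-", "other",
                 "not_a_PC", "not_a_PC", "not_a_PC"))
})

test_that("classification agrees with a per-cell brute-force oracle", {
  set.seed(11)
  pos <- random_positivity(200)
  lab <- classify_cells(pos)
  ora <- oracle_classify(pos)
  expect_equal(as.character(lab$lineage), ora$lineage)
  expect_equal(as.character(lab$pc_subtype), ora$pc_subtype)
})

test_that("marker fractions are percentages of Vim+ LP cells per patient", {
  panel <- tiny_panel()
  cells <- tiny_cells(panel, n = 50)
  pos <- random_positivity(50)
  pos[, "Vimentin"] <- rep(c(TRUE, FALSE), c(40, 10))
  pos[, "CD19"] <- rep(c(TRUE, FALSE, TRUE), c(10, 30, 10))
  pos[, "CD138"] <- FALSE   # keep lineages simple
  lab <- classify_cells(pos)
  fr <- marker_fractions(cells, pos, lab, targets = "CD19")
  expect_equal(fr$pct, 25)       # 10 CD19+ of 40 Vim+
  expect_equal(fr$n_vim, 40L)

  pos[, "CD19"] <- pos[, "Vimentin"]
  fr <- marker_fractions(cells, pos, classify_cells(pos), targets = "CD19")
  expect_equal(fr$pct, 100)

  pos[, "Vimentin"] <- FALSE
  expect_warning(fr <- marker_fractions(cells, pos, classify_cells(pos),
                                        targets = "CD19"),
                 "no Vim")
  expect_true(is.na(fr$pct))
})

test_that("PC subtype fractions sum to 100 and are order-invariant", {
  panel <- tiny_panel()
  cells <- tiny_cells(panel, n = 10)
  pos <- matrix(FALSE, 10, 9,
                dimnames = list(NULL, gateable_targets(panel)))
  pos[, "Vimentin"] <- TRUE
  pos[, "CD138"] <- TRUE
  pos[1:8, "CD45"] <- TRUE
  pos[c(1:5, 9, 10), "CD19"] <- c(rep(TRUE, 5), FALSE, FALSE)
  # 5 CD19+CD45+, 3 CD19-CD45+, 2 CD19-CD45-
  lab <- classify_cells(pos)
  fr <- pc_subtype_fractions(cells, lab)
  expect_equal(fr$pct, c(50, 30, 20, 0))
  expect_equal(sum(fr$pct), 100)

  perm <- sample(10)
  fr2 <- pc_subtype_fractions(cells[perm, ], lab[perm, ])
  expect_equal(fr2$pct, fr$pct)

  # all one subtype
  pos[, "CD19"] <- TRUE; pos[, "CD45"] <- TRUE
  expect_equal(pc_subtype_fractions(cells, classify_cells(pos))$pct,
               c(100, 0, 0, 0))

  # no PCs at all
  pos[, "CD138"] <- FALSE
  expect_warning(fr0 <- pc_subtype_fractions(cells, classify_cells(pos)), "no PCs")
  expect_true(all(is.na(fr0$pct)))
})

test_that("relative abundance rescales to a unit control median", {
  ra <- relative_abundance(3, c(1, 2, 3))
  expect_equal(ra$case, 1.5)
  expect_equal(ra$control, c(0.5, 1, 1.5))
  expect_equal(median(relative_abundance(c(1, 2, 3), c(1, 2, 3))$case), 1)
  expect_error(relative_abundance(1, c(0, 0)), class = "sscp_validation_error")
  expect_error(relative_abundance(1, numeric(0)), class = "sscp_validation_error")
})

test_that("subtype marker summaries report medians, percent positive and reference ratios", {
  panel <- tiny_panel()
  n <- 6
  cells <- tiny_cells(panel, n = n)
  cells$CD138 <- c(200, 200, 200, 180, 180, 180)
  attr(cells, "isotype_subtracted") <- TRUE
  cells[["Ms IgG1"]] <- cells[["Rb IgG"]] <- NULL
  pos <- matrix(TRUE, n, 9, dimnames = list(NULL, gateable_targets(panel)))
  pos[4:6, "CD19"] <- FALSE
  pos[4:6, "CD45"] <- FALSE
  lab <- classify_cells(pos)  # 3 CD19+CD45+, 3 CD19-CD45-

  s <- subtype_marker_summary(cells, pos, lab, targets = "CD138",
                              reference = "CD19+CD45+")
  early <- s[s$pc_subtype == "CD19+CD45+", ]
  late <- s[s$pc_subtype == "CD19-CD45-", ]
  expect_equal(early$median_level, 200)
  expect_equal(late$median_level, 180)
  expect_equal(early$rel_median_level, 1)
  expect_equal(late$rel_median_level, 0.9)
  expect_true(all(is.na(s$median_level[s$pc_subtype == "other"])))

  # single-cell subtype: the median is that cell's value
  pos2 <- pos; pos2[4:6, "CD45"] <- TRUE; pos2[5:6, "CD19"] <- TRUE
  lab2 <- classify_cells(pos2)
  s2 <- subtype_marker_summary(cells, pos2, lab2, targets = "CD138")
  expect_equal(s2$median_level[s2$pc_subtype == "CD19-CD45+"], 180)

  # reference subtype absent: normalisation error naming the patient
  lab3 <- classify_cells(pos)
  lab3$pc_subtype[lab3$pc_subtype == "CD19+CD45+"] <- "CD19-CD45-"
  expect_error(subtype_marker_summary(cells, pos, lab3, targets = "CD138",
                                      reference = "CD19+CD45+"),
               class = "sscp_validation_error")
})

test_that("planted per-cell positive rates are recovered from the summary", {
  panel <- tiny_panel()
  n <- 500
  set.seed(21)
  cells <- tiny_cells(panel, n = n)
  attr(cells, "isotype_subtracted") <- TRUE
  cells[["Ms IgG1"]] <- cells[["Rb IgG"]] <- NULL
  pos <- matrix(FALSE, n, 9, dimnames = list(NULL, gateable_targets(panel)))
  pos[, c("Vimentin", "CD138", "CD19", "CD45")] <- TRUE
  planted <- 0.30
  pos[, "CD27"] <- runif(n) < planted
  lab <- classify_cells(pos)
  s <- subtype_marker_summary(cells, pos, lab, targets = "CD27")
  got <- s$pct_positive[s$pc_subtype == "CD19+CD45+"]
  se <- 100 * sqrt(planted * (1 - planted) / n)
  expect_lt(abs(got - 100 * planted), 3 * se)
})
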
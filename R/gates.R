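# Marker gates: conjunctions of required signs over the positivity matrix.
# Gate definitions live in data (a named list, loadable from YAML), not in
# code, so other panels can be phenotyped with the same machinery.

#' Default gate library for colonic B-lineage phenotyping
#'
#' * `LP_immune`: Vimentin+ (lamina-propria residency),
#' * `PC`: Vimentin+ CD138+ plasma cells,
#' * `PB`: Vimentin+ CD19+ CD27+ CD38+ CD20- CD138- plasmablasts.
#'
#' Plasma-cell maturation subtypes are not gates of their own: they are read
#' off the CD19/CD45 signs of PC cells by [classify_cells()].
#'
#' @return named list of gates; each gate is a named character vector of
#'   `"+"`/`"-"` requirements.
#' @export
default_gates <- function() {
  list(
    LP_immune = c(Vimentin = "+"),
    PC = c(Vimentin = "+", CD138 = "+"),
    PB = c(Vimentin = "+", CD19 = "+", CD27 = "+", CD38 = "+",
           CD20 = "-", CD138 = "-")
  )
}

#' Read a gate library from a YAML file
#'
#' Expected layout: `gates: {PB: {CD19: "+", CD27: "+", ...}, ...}` (a
#' top-level `gates` mapping is optional).
#'
#' @param path YAML file.
#' @return named list of gates as in [default_gates()].
#' @export
read_gate_library <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$gates)) y <- y$gates
  if (!length(y)) abort_format("gate library is empty")
  lapply(y, function(g) {
    v <- unlist(g)
    if (!all(v %in% c("+", "-"))) {
      abort_config("gate requirements must be '+' or '-'")
    }
    v
  })
}

#' Evaluate a gate over positivity calls
#'
#' A cell satisfies a gate when every required sign matches its positivity
#' call; an empty gate is vacuously true (flagged with a warning).
#'
#' @param positivity logical matrix (cells x targets) or a single named
#'   logical vector for one cell.
#' @param gate named character vector of `"+"`/`"-"` requirements.
#' @return logical vector, one entry per cell.
#' @export
evaluate_gate <- function(positivity, gate) {
  if (is.null(dim(positivity))) {
    positivity <- matrix(positivity, nrow = 1,
                         dimnames = list(NULL, names(positivity)))
  }
  if (length(gate) == 0L) {
    warning("empty gate: vacuously true for every cell")
    return(rep(TRUE, nrow(positivity)))
  }
  unknown <- setdiff(names(gate), colnames(positivity))
  if (length(unknown)) {
    abort_config(paste0("gate references unknown target(s): ",
                        paste(unknown, collapse = ", ")))
  }
  want <- gate == "+"
  sub <- positivity[, names(gate), drop = FALSE]
  hit <- sub == matrix(want, nrow(sub), length(want), byrow = TRUE)
  rowSums(hit) == length(gate)
}
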
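# Structured condition helpers. Every user-facing validation failure carries a
# subclass so callers (and the CLI) can map it to an exit code.

sscp_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "sscp_error", "error", "condition")))
}

abort_format     <- function(msg) sscp_error(msg, "sscp_format_error")
abort_validation <- function(msg) sscp_error(msg, "sscp_validation_error")
abort_config     <- function(msg) sscp_error(msg, "sscp_config_error")
abort_usage      <- function(msg) sscp_error(msg, "sscp_usage_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fixed metadata columns of a cell table; everything else must be a panel target.
META_COLS <- c("cell_id", "patient_id", "condition", "fov_id",
               "x_um", "y_um", "area_um2")

# Delimiter by extension: .tsv/.txt tab, anything else comma.
.read_delim <- function(path, sep = NULL) {
  if (!file.exists(path)) abort_format(paste0("file not found: ", path))
  if (is.null(sep)) {
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  }
  utils::read.csv(path, sep = sep, check.names = FALSE, stringsAsFactors = FALSE)
}

# %.17g round-trips IEEE doubles exactly through text.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- NA_character_
  out
}

.write_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
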
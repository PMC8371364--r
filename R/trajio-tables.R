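# Tidy metric tables on disk: TSV, header row, floats at 6 significant
# digits, byte-identical output for identical input.

.index_signature <- function(df) {
  idx <- intersect(c("frame", "time_ns", "chain", "res_seq", "icode",
                     "res_name", "residue", "bond", "run", "metric"),
                   names(df))
  paste(sort(idx), collapse = ",")
}

#' Write metric series, residue profiles or occupancies as TSV
#'
#' Accepts one tidy table or a list of tables sharing a consistent index
#' (per-frame, per-residue, or per-bond); lists are row-bound. Floating-point
#' values are printed at 6 significant digits so identical inputs always give
#' bit-identical files.
#'
#' @param x A tibble, or a list of tibbles with the same index columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(x, path) {
  if (inherits(x, "data.frame")) x <- list(x)
  if (!is.list(x) || length(x) == 0) {
    abort("No metric series to write.", class = "btkloop_index_error")
  }
  sigs <- vapply(x, .index_signature, "")
  if (length(unique(sigs)) != 1L || !nzchar(sigs[1])) {
    abort(sprintf(
      "Metric tables have incompatible or missing index columns: %s",
      paste(unique(sigs), collapse = " vs ")), class = "btkloop_index_error")
  }
  df <- dplyr::bind_rows(x)
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      df[[j]] <- formatC(signif(df[[j]], 6), digits = 6, format = "g")
      df[[j]][df[[j]] %in% c("NA", " NA")] <- "NA"
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(path)
}

#' Read a metric TSV written by [write_metric_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_metric_table <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE))
}
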
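`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical key for a set of transcription factor labels
#'
#' Sets of TF labels are represented throughout the package as a single
#' string with the sorted, de-duplicated labels joined by `"+"` (e.g.
#' `"IKZF1+PAX5"`). The empty set maps to `""`.
#'
#' @param tfs character vector of TF labels (possibly empty).
#' @return a length-1 character key.
#' @export
tf_subset_key <- function(tfs) {
  tfs <- unique(as.character(tfs))
  tfs <- tfs[!is.na(tfs) & nzchar(tfs)]
  paste(sort(tfs), collapse = "+")
}

#' Split a TF subset key back into its labels
#' @param key key produced by [tf_subset_key()].
#' @return character vector of labels (length 0 for the empty key).
#' @export
tf_subset_labels <- function(key) {
  if (is.na(key) || !nzchar(key)) return(character(0))
  strsplit(key, "+", fixed = TRUE)[[1]]
}

config_error <- function(msg) {
  stop(errorCondition(msg, class = c("proxinet_config_error", "error", "condition")))
}

contract_error <- function(msg) {
  stop(errorCondition(msg, class = c("proxinet_contract_error", "error", "condition")))
}

parse_error <- function(msg) {
  stop(errorCondition(msg, class = c("proxinet_parse_error", "error", "condition")))
}

#' Distance from a genomic interval to a point
#'
#' Intervals are 0-based half-open `[start, end)`. The distance to a point
#' is 0 if the point lies inside the interval and the gap to the nearest
#' boundary otherwise, so a TSS at 10000 is 1000 bp from a peak
#' `[8000, 9000)`.
#'
#' @param start,end interval coordinates (vectors recycled against `pos`).
#' @param pos point position(s).
#' @return numeric vector of distances (>= 0).
#' @export
interval_point_distance <- function(start, end, pos) {
  pmax(start - pos, pos - end, 0)
}

# 0-based half-open data.frame -> GRanges (1-based closed internally)
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

stopifnot_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    contract_error(sprintf("%s is missing column(s): %s", what, paste(miss, collapse = ", ")))
  }
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}
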
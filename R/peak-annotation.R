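#' Read a peak file (BED or HOMER dialect)
#'
#' Internal coordinates are 0-based half-open. BED input passes through;
#' HOMER peak files (1-based, inclusive, comment lines starting with `#`)
#' are shifted to the internal convention. For BED the score column (5th)
#' is taken as the normalized tag count; for HOMER the 6th column.
#'
#' @param path file path.
#' @param dialect `"bed"` or `"homer"`.
#' @param tf TF label attached to every peak (default: file base name).
#' @return data.frame with columns `chrom`, `start`, `end`, `peak_id`,
#'   `tf`, `tags`.
#' @export
read_peaks <- function(path, dialect = c("bed", "homer"), tf = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) config_error(sprintf("peak file not found: %s", path))
  if (is.null(tf)) tf <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  is_data <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  rows <- which(is_data)
  if (!length(rows)) {
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      peak_id = character(0), tf = character(0), tags = numeric(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[rows], "\t| +")
  parse_row <- function(i) {
    f <- fields[[i]]
    line_no <- rows[i]
    if (dialect == "bed") {
      if (length(f) < 3) parse_error(sprintf("line %d: expected >= 3 BED fields", line_no))
      start <- suppressWarnings(as.integer(f[2])); end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) parse_error(sprintf("line %d: non-numeric coordinates", line_no))
      if (end <= start) parse_error(sprintf("line %d: end <= start", line_no))
      tags <- if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else NA_real_
      id <- if (length(f) >= 4 && nzchar(f[4]) && f[4] != ".") f[4] else sprintf("peak_%d", i)
      c(f[1], start, end, id, ifelse(is.na(tags), 0, tags))
    } else {
      if (length(f) < 4) parse_error(sprintf("line %d: expected >= 4 HOMER fields", line_no))
      start <- suppressWarnings(as.integer(f[3])); end <- suppressWarnings(as.integer(f[4]))
      if (is.na(start) || is.na(end)) parse_error(sprintf("line %d: non-numeric coordinates", line_no))
      start <- start - 1L  # 1-based inclusive -> 0-based half-open
      if (end <= start) parse_error(sprintf("line %d: end <= start", line_no))
      tags <- if (length(f) >= 6) suppressWarnings(as.numeric(f[6])) else NA_real_
      c(f[2], start, end, f[1], ifelse(is.na(tags), 0, tags))
    }
  }
  m <- t(vapply(seq_along(rows), parse_row, character(5)))
  data.frame(chrom = m[, 1], start = as.integer(m[, 2]), end = as.integer(m[, 3]),
             peak_id = m[, 4], tf = tf, tags = as.numeric(m[, 5]),
             stringsAsFactors = FALSE)
}

#' Write peaks as 6-column BED
#'
#' Columns: chrom, start, end, peak id, tag count (score), TF label.
#' @param peaks peak data.frame.
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  stopifnot_cols(peaks, c("chrom", "start", "end", "peak_id", "tf", "tags"), "peaks")
  write.table(peaks[, c("chrom", "start", "end", "peak_id", "tags", "tf")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter peaks on normalized tag count
#'
#' Keeps exactly the peaks with `tags >= min_tags` (the standard published
#' cut is 15 normalized tags, or 10 for weaker datasets); input order is
#' preserved.
#'
#' @param peaks peak data.frame.
#' @param min_tags threshold.
#' @return filtered peak data.frame.
#' @export
filter_peaks <- function(peaks, min_tags) {
  stopifnot_cols(peaks, c("tags"), "peaks")
  out <- peaks[peaks$tags >= min_tags, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge peak sets across TFs into overlap components
#'
#' Overlapping peaks (>= 1 shared bp, same chromosome) are merged
#' transitively, i.e. merged peaks are the connected components of the
#' overlap graph, the observable behavior of HOMER's mergePeaks on chains.
#' Each merged peak spans the union of its members and records which TFs
#' contributed; every input peak belongs to exactly one merged peak.
#'
#' @param peaks either a single peak data.frame with a `tf` column or a
#'   named list of peak data.frames (names used as TF labels).
#' @return data.frame: `merged_id`, `chrom`, `start`, `end`, `members`
#'   ([tf_subset_key()] of contributing TFs), `n_peaks`, `peak_ids`
#'   (comma-separated).
#' @export
merge_peak_sets <- function(peaks) {
  peaks <- bind_peak_sets(peaks)
  if (nrow(peaks) == 0) {
    return(data.frame(merged_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0), members = character(0),
                      n_peaks = integer(0), peak_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- as_granges0(peaks)
  # min.gapwidth = 0: merge only ranges sharing >= 1 bp, never book-ended ones
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hit <- GenomicRanges::findOverlaps(gr, red)
  comp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
  stopifnot(length(comp) == nrow(peaks))
  idx <- split(seq_len(nrow(peaks)), comp)
  out <- data.frame(
    merged_id = sprintf("M%06d", seq_along(idx)),
    chrom = as.character(GenomicRanges::seqnames(red))[as.integer(names(idx))],
    start = GenomicRanges::start(red)[as.integer(names(idx))] - 1L,
    end = GenomicRanges::end(red)[as.integer(names(idx))],
    members = vapply(idx, function(i) tf_subset_key(peaks$tf[i]), ""),
    n_peaks = lengths(idx),
    peak_ids = vapply(idx, function(i) paste(peaks$peak_id[i], collapse = ","), ""),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

bind_peak_sets <- function(peaks) {
  if (is.data.frame(peaks)) {
    stopifnot_cols(peaks, c("chrom", "start", "end", "peak_id", "tf"), "peaks")
    return(peaks)
  }
  if (is.null(names(peaks))) contract_error("list of peak sets must be named by TF")
  do.call(rbind, lapply(names(peaks), function(tf) {
    df <- peaks[[tf]]
    df$tf <- tf
    df
  }))
}

#' Count merged peaks per TF combination
#'
#' The Venn/UpSet tally: how many merged peaks carry exactly each non-empty
#' TF subset. Counts sum to the number of merged peaks.
#'
#' @param merged output of [merge_peak_sets()].
#' @return data.frame `members`, `n`, sorted by decreasing count.
#' @export
combination_counts <- function(merged) {
  stopifnot_cols(merged, "members", "merged peaks")
  if (nrow(merged) == 0) {
    return(data.frame(members = character(0), n = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(merged$members)
  out <- data.frame(members = names(tab), n = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n, out$members), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate peaks to TSS-proximal genes
#'
#' A peak is proximal to a gene if the distance between the peak interval
#' and the gene's TSS (0 when the TSS lies inside the peak) is at most
#' `window`, symmetric upstream/downstream. By default each proximal peak
#' is assigned to the single closest TSS, ties broken deterministically by
#' the lexicographically smaller gene id; `all_in_window = TRUE` assigns
#' to every gene within the window instead.
#'
#' @param peaks peak data.frame.
#' @param genes gene model data.frame (`gene_id`, `chrom`, `tss`).
#' @param window proximity window in bp (default 2500).
#' @param all_in_window assign to all genes in the window rather than the
#'   closest one.
#' @return assignment data.frame: `gene_id`, `tf`, `evidence` (always
#'   `"proximal"`), `peak_id`, `distance`.
#' @export
annotate_proximal <- function(peaks, genes, window = 2500, all_in_window = FALSE) {
  stopifnot_cols(peaks, c("chrom", "start", "end", "peak_id", "tf"), "peaks")
  stopifnot_cols(genes, c("gene_id", "chrom", "tss"), "genes")
  empty <- data.frame(gene_id = character(0), tf = character(0), evidence = character(0),
                      peak_id = character(0), distance = numeric(0), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(genes) == 0) return(empty)
  # widen by window + 1 bp and filter on the exact distance afterwards, so
  # boundary TSSs (distance exactly == window) are never missed
  grown <- GenomicRanges::GRanges(peaks$chrom,
                                  IRanges::IRanges(pmax(peaks$start - window - 1, 0) + 1L,
                                                   peaks$end + window + 1L))
  tss <- GenomicRanges::GRanges(genes$chrom, IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  hit <- GenomicRanges::findOverlaps(grown, tss)
  if (!length(hit)) return(empty)
  pi <- S4Vectors::queryHits(hit); gi <- S4Vectors::subjectHits(hit)
  d <- interval_point_distance(peaks$start[pi], peaks$end[pi], genes$tss[gi])
  ok <- d <= window
  pi <- pi[ok]; gi <- gi[ok]; d <- d[ok]
  if (!length(pi)) return(empty)
  if (!all_in_window) {
    # single closest TSS per peak; ties -> smaller gene id
    ord <- order(pi, d, genes$gene_id[gi])
    keep <- ord[!duplicated(pi[ord])]
    pi <- pi[keep]; gi <- gi[keep]; d <- d[keep]
  }
  out <- data.frame(gene_id = genes$gene_id[gi], tf = peaks$tf[pi],
                    evidence = "proximal", peak_id = peaks$peak_id[pi],
                    distance = d, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$tf, out$peak_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Split peaks into TSS-proximal and distal subsets
#'
#' Convenience partition ahead of loop-mediated assignment: a peak is
#' distal when no TSS lies within `window` of it.
#'
#' @inheritParams annotate_proximal
#' @return list with `proximal` and `distal` peak data.frames.
#' @export
split_peaks_by_tss <- function(peaks, genes, window = 2500) {
  ann <- annotate_proximal(peaks, genes, window = window, all_in_window = TRUE)
  prox_ids <- unique(ann$peak_id)
  list(proximal = peaks[peaks$peak_id %in% prox_ids, , drop = FALSE],
       distal = peaks[!peaks$peak_id %in% prox_ids, , drop = FALSE])
}
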
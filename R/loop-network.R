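#' Normalize and validate a chromatin-loop table
#'
#' Orders anchors by (chrom, start), fills missing ids, and warns when an
#' intra-chromosomal loop has anchor separation below two bins (loops are
#' conventionally called between regions at least 10 kb apart at 5 kb
#' resolution); short loops are tolerated to accommodate format dialects.
#'
#' @param loops BEDPE-like data.frame: `chrom1,start1,end1,chrom2,start2,end2`
#'   plus optional `loop_id`, `mark`, `significance`.
#' @param bin_size bin size in bp used for the separation check.
#' @return normalized loop data.frame.
#' @export
normalize_loops <- function(loops, bin_size = 5000) {
  stopifnot_cols(loops, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"), "loops")
  if (is.null(loops$loop_id)) loops$loop_id <- sprintf("L%05d", seq_len(nrow(loops)))
  if (is.null(loops$mark)) loops$mark <- NA_character_
  if (is.null(loops$significance)) loops$significance <- NA_real_
  swap <- loops$chrom1 > loops$chrom2 |
    (loops$chrom1 == loops$chrom2 & loops$start1 > loops$start2)
  if (any(swap)) {
    tmp <- loops[swap, c("chrom1", "start1", "end1")]
    loops[swap, c("chrom1", "start1", "end1")] <- loops[swap, c("chrom2", "start2", "end2")]
    loops[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  close_ <- loops$chrom1 == loops$chrom2 &
    (loops$start2 - loops$start1) < 2 * bin_size
  if (any(close_)) {
    warning(sprintf("%d intra-chromosomal loop(s) closer than 2 bins retained", sum(close_)),
            call. = FALSE)
  }
  rownames(loops) <- NULL
  loops
}

#' Merge loop sets across replicates at one-bin tolerance
#'
#' Two loops match when they lie on the same chromosome pair and both
#' anchor1-anchor1 and anchor2-anchor2 start offsets are at most one
#' `bin_size`; matching is closed transitively (connected components).
#' A merged loop spans the union of its members' anchors, keeps the
#' smallest significance, and records how many replicates support it.
#' Unmatched loops pass through unchanged. The result is independent of
#' replicate order and idempotent at the same tolerance.
#'
#' @param loop_sets a single loop data.frame or a (optionally named) list
#'   of per-replicate loop data.frames.
#' @param bin_size bin size in bp (default 5000).
#' @return merged loop data.frame with `n_replicates` and `n_members`.
#' @export
merge_loops <- function(loop_sets, bin_size = 5000) {
  if (is.data.frame(loop_sets)) loop_sets <- list(loop_sets)
  if (is.null(names(loop_sets))) names(loop_sets) <- sprintf("rep%d", seq_along(loop_sets))
  all <- do.call(rbind, lapply(names(loop_sets), function(nm) {
    df <- normalize_loops(loop_sets[[nm]], bin_size = bin_size)
    if (nrow(df)) df$replicate <- nm else df$replicate <- character(0)
    df
  }))
  if (is.null(all) || nrow(all) == 0) {
    out <- data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
                      chrom2 = character(0), start2 = integer(0), end2 = integer(0),
                      loop_id = character(0), mark = character(0), significance = numeric(0),
                      n_replicates = integer(0), n_members = integer(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  n <- nrow(all)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union_ <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[rj] <<- ri }

  groups <- split(seq_len(n), paste(all$chrom1, all$chrom2))
  for (g in groups) {
    if (length(g) < 2) next
    s1 <- all$start1[g]; s2 <- all$start2[g]
    for (a in seq_along(g)[-length(g)]) {
      b <- (a + 1):length(g)
      hit <- b[abs(s1[b] - s1[a]) <= bin_size & abs(s2[b] - s2[a]) <= bin_size]
      for (h in hit) union_(g[a], g[h])
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  idx <- split(seq_len(n), comp)
  out <- do.call(rbind, lapply(seq_along(idx), function(k) {
    i <- idx[[k]]
    data.frame(
      chrom1 = all$chrom1[i[1]], start1 = min(all$start1[i]), end1 = max(all$end1[i]),
      chrom2 = all$chrom2[i[1]], start2 = min(all$start2[i]), end2 = max(all$end2[i]),
      loop_id = sprintf("ML%05d", k),
      mark = all$mark[i[1]],
      significance = suppressWarnings(min(all$significance[i], na.rm = TRUE)),
      n_replicates = length(unique(all$replicate[i])),
      n_members = length(i),
      stringsAsFactors = FALSE
    )
  }))
  out$significance[!is.finite(out$significance)] <- NA_real_
  out <- out[order(out$chrom1, out$start1, out$chrom2, out$start2), , drop = FALSE]
  out$loop_id <- sprintf("ML%05d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

loop_anchor_table <- function(loops) {
  if (nrow(loops) == 0) {
    return(data.frame(loop_id = character(0), side = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0), stringsAsFactors = FALSE))
  }
  rbind(
    data.frame(loop_id = loops$loop_id, side = 1L, chrom = loops$chrom1,
               start = loops$start1, end = loops$end1, stringsAsFactors = FALSE),
    data.frame(loop_id = loops$loop_id, side = 2L, chrom = loops$chrom2,
               start = loops$start2, end = loops$end2, stringsAsFactors = FALSE)
  )
}

anchor_key <- function(chrom, start, end) sprintf("%s:%d-%d", chrom, start, end)

#' Classify loop anchors as TSS-proximal or distal
#'
#' An anchor is TSS-proximal when at least one gene TSS lies within
#' `tss_window` of the anchor interval (distance 0 if the TSS is inside);
#' proximal anchors list every such gene. All other anchors are distal.
#'
#' @param loops loop data.frame (merged or raw).
#' @param genes gene model data.frame.
#' @param tss_window window in bp (default 2500).
#' @return data.frame with one row per distinct anchor: `anchor_id`,
#'   `chrom`, `start`, `end`, `class` (`"tss_proximal"`/`"distal"`),
#'   `gene_ids` (comma-separated, `""` for distal).
#' @export
classify_anchors <- function(loops, genes, tss_window = 2500) {
  stopifnot_cols(genes, c("gene_id", "chrom", "tss"), "genes")
  anc <- loop_anchor_table(loops)
  anc$anchor_id <- anchor_key(anc$chrom, anc$start, anc$end)
  uni <- anc[!duplicated(anc$anchor_id), c("anchor_id", "chrom", "start", "end")]
  if (nrow(uni) == 0) {
    uni$class <- character(0); uni$gene_ids <- character(0)
    return(uni)
  }
  fake_peaks <- data.frame(chrom = uni$chrom, start = uni$start, end = uni$end,
                           peak_id = uni$anchor_id, tf = "anchor", stringsAsFactors = FALSE)
  ann <- annotate_proximal(fake_peaks, genes, window = tss_window, all_in_window = TRUE)
  gene_map <- split(ann$gene_id, ann$peak_id)
  uni$gene_ids <- vapply(uni$anchor_id, function(a) {
    paste(sort(unique(gene_map[[a]])), collapse = ",")
  }, "")
  uni$class <- ifelse(nzchar(uni$gene_ids), "tss_proximal", "distal")
  uni <- uni[, c("anchor_id", "chrom", "start", "end", "class", "gene_ids")]
  rownames(uni) <- NULL
  uni
}

# TF subset present at each loop anchor (>= 1 bp peak overlap)
anchor_tf_sets <- function(loops, peaks) {
  anc <- loop_anchor_table(loops)
  key <- paste(anc$loop_id, anc$side)
  sets <- setNames(vector("list", length(key)), key)
  if (nrow(anc) && nrow(peaks)) {
    hit <- GenomicRanges::findOverlaps(as_granges0(anc), as_granges0(peaks))
    if (length(hit)) {
      found <- split(peaks$tf[S4Vectors::subjectHits(hit)], key[S4Vectors::queryHits(hit)])
      sets[names(found)] <- found
    }
  }
  list(anchors = anc, key = key, sets = sets)
}

#' Count loops by the TF combination at their two anchor points
#'
#' A TF is present at an anchor when at least one of its peaks overlaps
#' the anchor interval by >= 1 bp. Loops with no TF at either anchor are
#' excluded from the tally (and reported). By default anchor-pair patterns
#' are unordered (a loop has no intrinsic direction), so pattern
#' `(S1, S2)` and `(S2, S1)` pool; `ordered = TRUE` keeps anchor1/anchor2
#' as given.
#'
#' @param loops loop data.frame.
#' @param peaks (filtered) peak data.frame with `tf` column.
#' @param ordered count ordered anchor patterns instead.
#' @return list with `counts` (data.frame `ap1`, `ap2`, `pattern`, `n`)
#'   and `n_excluded` (loops with both anchors TF-free).
#' @export
anchor_tf_combinations <- function(loops, peaks, ordered = FALSE) {
  ats <- anchor_tf_sets(loops, peaks)
  k1 <- vapply(paste(loops$loop_id, 1L), function(k) tf_subset_key(ats$sets[[k]]), "")
  k2 <- vapply(paste(loops$loop_id, 2L), function(k) tf_subset_key(ats$sets[[k]]), "")
  keep <- nzchar(k1) | nzchar(k2)
  a <- k1[keep]; b <- k2[keep]
  if (!ordered) {
    # canonical order: empty subset last, otherwise lexicographic
    swap <- (!nzchar(a) & nzchar(b)) | (nzchar(a) & nzchar(b) & a > b)
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  pat <- paste(ifelse(nzchar(a), a, "(none)"), ifelse(nzchar(b), b, "(none)"), sep = " | ")
  tab <- table(pat)
  first <- !duplicated(pat)
  counts <- data.frame(ap1 = a[first], ap2 = b[first], pattern = pat[first],
                       stringsAsFactors = FALSE)
  counts$n <- as.integer(tab[counts$pattern])
  counts <- counts[order(-counts$n, counts$pattern), , drop = FALSE]
  rownames(counts) <- NULL
  list(counts = counts, n_excluded = sum(!keep))
}

#' Assign distal peaks to genes through chromatin loops
#'
#' A distal peak overlapping (>= 1 bp) a loop anchor whose partner anchor
#' is TSS-proximal is assigned to every gene of that partner anchor, with
#' evidence `"loop"`. Distal peaks overlapping no anchor, or only anchors
#' whose partners are all distal, are discarded -- distal binding without
#' an interaction to a promoter is uninterpretable at this resolution.
#' When a peak overlaps anchors of several loops all resulting gene
#' assignments are kept.
#'
#' @param peaks distal peak data.frame (see [split_peaks_by_tss()]).
#' @param loops loop data.frame.
#' @param anchor_classes output of [classify_anchors()] on the same loops.
#' @return list with `assignments` (gene_id, tf, evidence, peak_id) and
#'   `discarded` (peak ids never assigned).
#' @export
assign_distal_peaks <- function(peaks, loops, anchor_classes) {
  stopifnot_cols(anchor_classes, c("anchor_id", "class", "gene_ids"), "anchor_classes")
  empty <- data.frame(gene_id = character(0), tf = character(0), evidence = character(0),
                      peak_id = character(0), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0 || nrow(loops) == 0) {
    return(list(assignments = empty, discarded = unique(peaks$peak_id)))
  }
  anc <- loop_anchor_table(loops)
  anc$anchor_id <- anchor_key(anc$chrom, anc$start, anc$end)
  partner <- ifelse(anc$side == 1L, 2L, 1L)
  partner_row <- match(paste(anc$loop_id, partner), paste(anc$loop_id, anc$side))
  anc$partner_id <- anc$anchor_id[partner_row]
  cls <- setNames(anchor_classes$class, anchor_classes$anchor_id)
  gns <- setNames(anchor_classes$gene_ids, anchor_classes$anchor_id)

  hit <- GenomicRanges::findOverlaps(as_granges0(peaks), as_granges0(anc))
  assigned <- empty
  if (length(hit)) {
    pi <- S4Vectors::queryHits(hit); ai <- S4Vectors::subjectHits(hit)
    ok <- cls[anc$partner_id[ai]] == "tss_proximal"
    pi <- pi[ok]; ai <- ai[ok]
    if (length(pi)) {
      gene_str <- gns[anc$partner_id[ai]]
      gene_list <- strsplit(gene_str, ",", fixed = TRUE)
      reps <- lengths(gene_list)
      assigned <- data.frame(
        gene_id = unlist(gene_list),
        tf = rep(peaks$tf[pi], reps),
        evidence = "loop",
        peak_id = rep(peaks$peak_id[pi], reps),
        stringsAsFactors = FALSE
      )
      assigned <- unique(assigned)
      assigned <- assigned[order(assigned$gene_id, assigned$tf, assigned$peak_id), , drop = FALSE]
      rownames(assigned) <- NULL
    }
  }
  list(assignments = assigned,
       discarded = setdiff(unique(peaks$peak_id), unique(assigned$peak_id)))
}

#' Build co-bound gene sets from proximity and loop assignments
#'
#' A gene's bound-TF set is the union over both evidence types ("annotated
#' to the same gene independent of position"); genes are then partitioned
#' by their exact bound set.
#'
#' @param ... any number of assignment data.frames (from
#'   [annotate_proximal()] and [assign_distal_peaks()]).
#' @return list with `genes` (data.frame `gene_id`, `tf_set`, `n_tfs`) and
#'   `by_subset` (named list: [tf_subset_key()] -> gene-id vector).
#' @export
cobound_genes <- function(...) {
  parts <- Filter(function(d) !is.null(d) && nrow(d) > 0, list(...))
  if (!length(parts)) {
    return(list(genes = data.frame(gene_id = character(0), tf_set = character(0),
                                   n_tfs = integer(0), stringsAsFactors = FALSE),
                by_subset = list()))
  }
  asn <- do.call(rbind, lapply(parts, function(d) d[, c("gene_id", "tf")]))
  tf_map <- split(asn$tf, asn$gene_id)
  genes <- data.frame(
    gene_id = names(tf_map),
    tf_set = vapply(tf_map, tf_subset_key, ""),
    stringsAsFactors = FALSE
  )
  genes$n_tfs <- lengths(lapply(genes$tf_set, tf_subset_labels))
  genes <- genes[order(genes$gene_id), , drop = FALSE]
  rownames(genes) <- NULL
  list(genes = genes, by_subset = split(genes$gene_id, genes$tf_set))
}

#' Restrict a gene-category table to unambiguous genes
#'
#' Given gene-to-category assignments (categories may be defined over
#' several peak classes), genes hitting more than one distinct category
#' are excluded and tallied; the exact-bound-set partition from
#' [cobound_genes()] is inherently unique and passes through unchanged.
#'
#' @param gene_categories data.frame with `gene_id` and `category`.
#' @return list with `assigned` (unique gene_id/category rows),
#'   `excluded_genes` and `n_excluded`.
#' @export
unique_category_genes <- function(gene_categories) {
  stopifnot_cols(gene_categories, c("gene_id", "category"), "gene_categories")
  u <- unique(gene_categories[, c("gene_id", "category")])
  n_cat <- table(u$gene_id)
  ambiguous <- names(n_cat)[n_cat > 1]
  assigned <- u[!u$gene_id %in% ambiguous, , drop = FALSE]
  assigned <- assigned[order(assigned$gene_id), , drop = FALSE]
  rownames(assigned) <- NULL
  list(assigned = assigned, excluded_genes = ambiguous, n_excluded = length(ambiguous))
}

#' Read/write BEDPE loop files
#'
#' Columns: chrom1, start1, end1, chrom2, start2, end2, name, score
#' (significance), plus optional mark.
#' @param path file path.
#' @param loops loop data.frame (for writing).
#' @return `read_loops_bedpe`: a loop data.frame.
#' @export
read_loops_bedpe <- function(path) {
  if (!file.exists(path)) config_error(sprintf("loop file not found: %s", path))
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6) parse_error("BEDPE needs at least 6 columns")
  names(df)[1:6] <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2")
  if (ncol(df) >= 7) names(df)[7] <- "loop_id"
  if (ncol(df) >= 8) names(df)[8] <- "significance"
  if (ncol(df) >= 9) names(df)[9] <- "mark"
  normalize_loops(df)
}

#' @rdname read_loops_bedpe
#' @export
write_loops_bedpe <- function(loops, path) {
  stopifnot_cols(loops, c("chrom1", "start1", "end1", "chrom2", "start2", "end2"), "loops")
  df <- loops[, c("chrom1", "start1", "end1", "chrom2", "start2", "end2")]
  df$name <- loops$loop_id %||% sprintf("L%05d", seq_len(nrow(loops)))
  df$score <- loops$significance %||% NA_real_
  df$mark <- loops$mark %||% NA_character_
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
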
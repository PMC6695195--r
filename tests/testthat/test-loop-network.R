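mk_loops <- function(s1, s2, bin = 5000, chrom = "chr1", ids = NULL) {
  data.frame(chrom1 = chrom, start1 = s1, end1 = s1 + bin,
             chrom2 = chrom, start2 = s2, end2 = s2 + bin,
             loop_id = ids %||% sprintf("l%d", seq_along(s1)),
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("loop merging joins anchors within one bin and not beyond", {
  a <- mk_loops(0, 50000)
  b <- mk_loops(5000, 55000)
  m <- merge_loops(list(a, b), bin_size = 5000)
  expect_equal(nrow(m), 1)            # offsets of exactly 1 bin merge
  expect_equal(m$start1, 0); expect_equal(m$end1, 10000)
  expect_equal(m$start2, 50000); expect_equal(m$end2, 60000)
  expect_equal(m$n_replicates, 2)

  c2 <- mk_loops(10000, 60000)
  m2 <- merge_loops(list(a, c2), bin_size = 5000)
  expect_equal(nrow(m2), 2)           # 2-bin offsets do not merge

  m3 <- merge_loops(list(a, a), bin_size = 5000)
  expect_equal(nrow(m3), 1)           # identical loops collapse
  expect_equal(m3$n_replicates, 2)

  # both anchor offsets must be within a bin
  d <- mk_loops(5000, 65000)
  expect_equal(nrow(merge_loops(list(a, d), bin_size = 5000)), 2)
})

test_that("loop merging matches the brute-force oracle and is order invariant", {
  set.seed(201)
  for (i in 1:40) {
    lp <- random_loop_instance(sample(2:30, 1))
    got <- merge_loops(lp, bin_size = 1000)
    want <- oracle_merge_loops(lp, bin_size = 1000)
    key <- function(d) sort(paste(d$chrom1, d$start1, d$end1, d$start2, d$end2, d$n_members))
    expect_equal(key(got), key(want))
  }
  lp <- random_loop_instance(25)
  m1 <- merge_loops(lp, bin_size = 1000)
  m2 <- merge_loops(lp[sample(nrow(lp)), ], bin_size = 1000)
  key <- function(d) sort(paste(d$start1, d$start2, d$n_members))
  expect_equal(key(m1), key(m2))
  # idempotence: merged output has no remaining matches at the same tolerance
  again <- merge_loops(m1, bin_size = 1000)
  expect_equal(nrow(again), nrow(m1))
})

test_that("anchor classification applies the TSS window to the anchor interval", {
  genes <- data.frame(gene_id = c("G1", "G2", "G3"), chrom = "chr1",
                      tss = c(12000, 17400, 17600))
  lp <- mk_loops(10000, 60000)
  ac <- classify_anchors(lp, genes, tss_window = 2500)
  a1 <- ac[ac$start == 10000, ]
  # G1 inside (distance 0), G2 at gap 2400, G3 at gap 2600
  expect_equal(a1$class, "tss_proximal")
  expect_setequal(strsplit(a1$gene_ids, ",")[[1]], c("G1", "G2"))
  a2 <- ac[ac$start == 60000, ]
  expect_equal(a2$class, "distal")
  expect_equal(a2$gene_ids, "")
})

test_that("anchor TF combinations count unordered patterns and exclude TF-free loops", {
  lp <- mk_loops(c(0, 100000), c(50000, 150000))
  pk <- data.frame(chrom = "chr1", start = c(1000, 2000), end = c(1300, 2300),
                   peak_id = c("p1", "p2"), tf = c("PAX5", "EBF1"), tags = 20)
  res <- anchor_tf_combinations(lp, pk)
  expect_equal(res$n_excluded, 1)  # second loop touches no peak
  expect_equal(nrow(res$counts), 1)
  expect_equal(res$counts$ap1, "EBF1+PAX5")
  expect_equal(res$counts$ap2, "")
  expect_equal(res$counts$n, 1L)

  # unordered: swapping the anchors lands in the same bucket
  lp2 <- mk_loops(c(0, 100000), c(50000, 150000))
  pk2 <- rbind(pk, data.frame(chrom = "chr1", start = 151000, end = 151300,
                              peak_id = "p3", tf = "PAX5", tags = 20),
               data.frame(chrom = "chr1", start = 151500, end = 151800,
                          peak_id = "p4", tf = "EBF1", tags = 20))
  res2 <- anchor_tf_combinations(lp2, pk2)
  expect_equal(res2$counts$n, 2L)
  expect_equal(nrow(res2$counts), 1)
  res2o <- anchor_tf_combinations(lp2, pk2, ordered = TRUE)
  expect_equal(sort(res2o$counts$n), c(1L, 1L))
})

test_that("anchor TF combinations match exhaustive enumeration on random instances", {
  set.seed(202)
  for (i in 1:30) {
    lp <- random_loop_instance(sample(2:30, 1))
    pk <- random_peak_instance(sample(5:40, 1), span = 35000)
    pk$chrom <- "chr1"
    got <- anchor_tf_combinations(lp, pk)
    want <- t(vapply(seq_len(nrow(lp)), function(j) oracle_anchor_sets(lp[j, ], pk),
                     character(2)))
    keep <- nzchar(want[, 1]) | nzchar(want[, 2])
    expect_equal(got$n_excluded, sum(!keep))
    w <- want[keep, , drop = FALSE]
    if (nrow(w) == 0) {
      expect_equal(nrow(got$counts), 0)
    } else {
      pat <- apply(w, 1, function(r) {
        r <- r[order(!nzchar(r), r)]  # empty subset sorts last
        paste(ifelse(nzchar(r), r, "(none)"), collapse = " | ")
      })
      wt <- table(pat)
      expect_setequal(got$counts$pattern, names(wt))
      expect_equal(got$counts$n[match(names(wt), got$counts$pattern)],
                   as.integer(wt), ignore_attr = TRUE)
    }
    expect_equal(sum(got$counts$n) + got$n_excluded, nrow(lp))
  }
})

test_that("distal peaks are assigned through loops to partner-anchor genes or discarded", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", tss = 52000)
  lp <- mk_loops(0, 50000)  # anchor2 contains the TSS
  ac <- classify_anchors(lp, genes)
  pk <- data.frame(chrom = "chr1", start = c(1000, 200000), end = c(1300, 200300),
                   peak_id = c("on_anchor", "nowhere"), tf = "PAX5", tags = 20)
  res <- assign_distal_peaks(pk, lp, ac)
  expect_equal(res$assignments$gene_id, "G1")
  expect_equal(res$assignments$evidence, "loop")
  expect_equal(res$assignments$peak_id, "on_anchor")
  expect_equal(res$discarded, "nowhere")

  # peak on an anchor whose partners are all distal is discarded too
  genes2 <- data.frame(gene_id = "G1", chrom = "chr1", tss = 1e6)
  ac2 <- classify_anchors(lp, genes2)
  res2 <- assign_distal_peaks(pk, lp, ac2)
  expect_equal(nrow(res2$assignments), 0)
  expect_setequal(res2$discarded, c("on_anchor", "nowhere"))

  # two loops from one anchor to two proximal partners: union of genes
  genes3 <- data.frame(gene_id = c("Ga", "Gb"), chrom = "chr1", tss = c(52000, 102000))
  lp3 <- mk_loops(c(0, 0), c(50000, 100000))
  ac3 <- classify_anchors(lp3, genes3)
  res3 <- assign_distal_peaks(pk[1, ], lp3, ac3)
  expect_setequal(res3$assignments$gene_id, c("Ga", "Gb"))

  # accounting: discarded + assigned = distal peaks
  expect_equal(length(res$discarded) + length(unique(res$assignments$peak_id)), nrow(pk))
})

test_that("co-bound gene sets union proximity and loop evidence", {
  prox <- data.frame(gene_id = "G1", tf = "PAX5", evidence = "proximal",
                     peak_id = "p1", distance = 10)
  loopa <- data.frame(gene_id = c("G1", "G2"), tf = c("RUNX1", "IKZF1"),
                      evidence = "loop", peak_id = c("p2", "p3"))
  cb <- cobound_genes(prox, loopa)
  expect_equal(cb$genes$tf_set[cb$genes$gene_id == "G1"], "PAX5+RUNX1")
  expect_setequal(cb$by_subset[["PAX5+RUNX1"]], "G1")
  expect_setequal(cb$by_subset[["IKZF1"]], "G2")
  # unbound genes absent
  expect_false("G3" %in% cb$genes$gene_id)
  # empty input
  cb0 <- cobound_genes(prox[0, ])
  expect_equal(nrow(cb0$genes), 0)
})

test_that("ambiguous multi-category genes are excluded and tallied", {
  gc <- data.frame(gene_id = c("G1", "G2", "G2", "G3", "G3"),
                   category = c("A", "A", "B", "C", "C"))
  res <- unique_category_genes(gc)
  expect_setequal(res$assigned$gene_id, c("G1", "G3"))
  expect_equal(res$excluded_genes, "G2")
  expect_equal(res$n_excluded, 1)
  res0 <- unique_category_genes(gc[0, ])
  expect_equal(nrow(res0$assigned), 0)
  expect_equal(res0$n_excluded, 0)
})

test_that("full recovery: co-bound sets equal the generator truth when all loops exist", {
  cfg <- sim_config(seed = 301, n_genes = 80, loop_rate = 1, n_distal_per_gene = 2)
  g <- generate_genome(cfg)
  pl <- generate_peaks_and_loops(cfg, g)
  loops <- merge_loops(pl$loops, bin_size = cfg$bin_size)
  prox <- annotate_proximal(pl$peaks, g, window = cfg$tss_window)
  parts <- split_peaks_by_tss(pl$peaks, g, window = cfg$tss_window)
  ac <- classify_anchors(loops, g, tss_window = cfg$tss_window)
  dist <- assign_distal_peaks(parts$distal, loops, ac)
  cb <- cobound_genes(prox, dist$assignments)
  want <- pl$truth$genes[nzchar(pl$truth$genes$bound_tfs), ]
  got <- setNames(cb$genes$tf_set, cb$genes$gene_id)
  expect_equal(unname(got[want$gene_id]), want$bound_tfs)
  expect_equal(nrow(cb$genes), nrow(want))
  expect_equal(length(dist$discarded), 0)

  # with loop_rate = 0 every distal peak is discarded
  cfg0 <- sim_config(seed = 301, n_genes = 80, loop_rate = 0, n_distal_per_gene = 2)
  pl0 <- generate_peaks_and_loops(cfg0, g)
  parts0 <- split_peaks_by_tss(pl0$peaks, g, window = cfg0$tss_window)
  res0 <- assign_distal_peaks(parts0$distal, pl0$loops,
                              classify_anchors(pl0$loops, g))
  expect_equal(nrow(res0$assignments), 0)
  expect_setequal(res0$discarded, parts0$distal$peak_id)
})

test_that("BEDPE round trip preserves loops and orders anchors", {
  lp <- mk_loops(c(50000, 0), c(0, 100000))  # first loop reversed on purpose
  f <- tempfile(fileext = ".bedpe")
  expect_warning(norm <- normalize_loops(lp), NA)  # separation >= 2 bins: no warning
  write_loops_bedpe(norm, f)
  back <- read_loops_bedpe(f)
  expect_true(all(back$start1 <= back$start2))
  expect_equal(sort(back$start1), c(0, 0))
  expect_warning(normalize_loops(mk_loops(0, 5000)), "2 bins")
})
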
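mk_meta <- function(pax5, ikzf1 = rep("wildtype", length(pax5)),
                    fusion = rep("wildtype", length(pax5))) {
  data.frame(sample_id = sprintf("S%02d", seq_along(pax5)),
             PAX5 = pax5, IKZF1 = ikzf1, `ETV6-RUNX1` = fusion,
             cell_type = "tumor", check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("contrast sample selection excludes unknown-status samples", {
  meta <- mk_meta(c("mutated", "mutated", "unknown", "wildtype", "wildtype"))
  ct <- de_contrast(c(PAX5 = "mutated"), c(PAX5 = "wildtype"))
  grp <- select_samples(meta, ct)
  expect_setequal(grp$a, c("S01", "S02"))
  expect_setequal(grp$b, c("S04", "S05"))
  expect_equal(grp$n_excluded, 1)
  expect_equal(length(intersect(grp$a, grp$b)), 0)

  # double-mutant contrast: unknown fusion status drops the sample
  meta2 <- mk_meta(rep("mutated", 4), fusion = c("mutated", "unknown", "wildtype", "mutated"))
  ct2 <- de_contrast(c(PAX5 = "mutated", `ETV6-RUNX1` = "mutated"),
                     c(PAX5 = "mutated", `ETV6-RUNX1` = "wildtype"))
  grp2 <- select_samples(meta2, ct2)
  expect_setequal(grp2$a, c("S01", "S04"))
  expect_equal(grp2$b, "S03")
  expect_equal(grp2$n_excluded, 1)

  # empty group errors with the contrast name
  meta3 <- mk_meta(rep("wildtype", 3))
  err <- tryCatch(select_samples(meta3, ct), error = identity)
  expect_s3_class(err, "proxinet_contract_error")
  expect_match(conditionMessage(err), "PAX5")
})

test_that("expression filter requires min_count in at least min_samples", {
  m <- rbind(g1 = c(0, 12, 9), g2 = c(10, 10, 0), g3 = c(9, 9, 9))
  colnames(m) <- c("a", "b", "c")
  expect_equal(filter_expressed(m), "g2")          # g1 has only one sample >= 10
  expect_setequal(filter_expressed(m, min_count = 0), c("g1", "g2", "g3"))
  expect_equal(filter_expressed(m, min_count = 10, min_samples = 1, samples = c("b", "c")),
               c("g1", "g2"))
})

test_that("size factors recover exact library scaling", {
  set.seed(401)
  base <- rpois(300, 50) + 1
  m <- cbind(A = base, B = 2 * base)
  sf <- size_factors(m)
  expect_equal(unname(sf["B"] / sf["A"]), 2, tolerance = 1e-12)
})

test_that("log2 RPKM follows the definition and its scaling law", {
  m <- matrix(c(100, 0), 1, 2, dimnames = list("g1", c("s1", "s2")))
  # library sizes 100 and 0-count sample: use a two-gene matrix for sane libs
  m2 <- rbind(g1 = c(100, 100), filler = c(1e6 - 100, 2e6 - 100))
  colnames(m2) <- c("s1", "s2")
  lr <- log2_rpkm(m2, c(g1 = 1000, filler = 1000))
  # count 100, length 1 kb, library 1e6 -> RPKM 100 -> log2(101)
  expect_equal(lr["g1", "s1"], log2(101), tolerance = 1e-12)
  # doubling the library halves RPKM
  expect_equal(lr["g1", "s2"], log2(51), tolerance = 1e-12)
  # zero count -> log2(pseudo)
  m3 <- rbind(g1 = c(0, 5), g2 = c(10, 10))
  colnames(m3) <- c("s1", "s2")
  expect_equal(log2_rpkm(m3, c(g1 = 500, g2 = 500))["g1", "s1"], 0)
})

test_that("Mann-Whitney is exact for small samples and monotone in shift", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$pvalue, 0.1, tolerance = 1e-12)  # 2 * 1/20 arrangements

  expect_equal(mann_whitney(1:5, 1:5 + 0)$pvalue, 1, tolerance = 1e-9)

  p_shift <- vapply(c(0, 2, 10), function(d) mann_whitney(1:6, 1:6 + d)$pvalue, 0)
  expect_true(all(diff(p_shift) <= 0))
})

test_that("group mean comparison averages the DE list per sample then tests", {
  lr <- rbind(g1 = c(1, 2, 5, 6), g2 = c(3, 4, 7, 8), g3 = c(0, 0, 0, 0))
  colnames(lr) <- sprintf("s%d", 1:4)
  gm <- group_mean_comparison(lr, c("g1", "g2"),
                              list(lo = c("s1", "s2"), hi = c("s3", "s4")))
  expect_equal(gm$sample_means$mean_log2_rpkm, c(2, 3, 6, 7))
  expect_equal(gm$tests$pvalue, 1 / 3, tolerance = 1e-12)  # exact 2-vs-2 extreme split
})

test_that("ECDF/KS comparisons behave at the degenerate extremes", {
  x <- setNames(rnorm(50), sprintf("a%d", 1:50))
  res <- responsiveness_ecdf(c(x, setNames(x, sprintf("b%d", 1:50))),
                             list(A = names(x), B = sprintf("b%d", 1:50)))
  expect_equal(res$tests$D, 0)
  expect_equal(res$tests$pvalue, 1)

  # disjoint supports -> D = 1
  v <- c(setNames(1:10, sprintf("a%d", 1:10)), setNames(101:110, sprintf("b%d", 1:10)))
  res2 <- responsiveness_ecdf(v, list(A = sprintf("a%d", 1:10), B = sprintf("b%d", 1:10)))
  expect_equal(res2$tests$D, 1)

  # well-separated distributions give large D with near certainty
  set.seed(402)
  v3 <- c(setNames(rnorm(200), sprintf("a%d", 1:200)),
          setNames(rnorm(200, 2), sprintf("b%d", 1:200)))
  res3 <- responsiveness_ecdf(v3, list(A = sprintf("a%d", 1:200), B = sprintf("b%d", 1:200)))
  expect_gt(res3$tests$D, 0.5)

  expect_error(responsiveness_ecdf(v, list(A = sprintf("a%d", 1:10), B = "b1")),
               class = "proxinet_contract_error")
})

test_that("threshold calls are boundary-inclusive and disjoint", {
  de <- data.frame(gene_id = sprintf("g%d", 1:5),
                   log2fc = c(1, 1, 0.9, -1.2, -0.5),
                   padj = c(0.05, 0.06, 0.01, 0.04, 0.01))
  calls <- de_threshold_calls(de, fdr = 0.05, min_fold = 2)
  expect_equal(calls$up, "g1")      # padj 0.05 and log2fc 1 both at the boundary
  expect_equal(calls$down, "g4")
  expect_equal(length(intersect(calls$up, calls$down)), 0)
})

test_that("NB differential expression recovers effects and respects the gene subset", {
  cfg <- sim_config(seed = 403, n_genes = 150, expr = list(log2fc = 2, n_per_class = 10))
  pl <- generate_peaks_and_loops(cfg, generate_genome(cfg))
  ex <- generate_expression(cfg, pl$truth$genes)
  a <- ex$meta$sample_id[ex$meta$PAX5 == "mutated"]
  b <- ex$meta$sample_id[ex$meta$PAX5 == "wildtype"]
  keep <- filter_expressed(ex$counts, samples = c(a, b))
  sub <- intersect(keep, ex$truth$gene_id)
  de <- nb_differential_expression(ex$counts, a, b, gene_subset = sub)
  expect_setequal(de$gene_id, setdiff(sub, de$gene_id[0]))
  # genes outside the subset are never tested
  de_small <- nb_differential_expression(ex$counts, a, b, gene_subset = sub[1:10])
  expect_equal(de_small$gene_id, sub[1:10])
  # adjusted p >= p and in [0,1]
  expect_true(all(de$padj >= de$pvalue - 1e-12, na.rm = TRUE))
  expect_true(all(de$pvalue >= 0 & de$pvalue <= 1, na.rm = TRUE))
  # BH monotone in p
  ord <- order(de$pvalue)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))
  # effect recovery: median |log2fc| of true DE genes near 2
  tde <- ex$truth$gene_id[ex$truth$is_de]
  expect_lt(abs(median(abs(de$log2fc[de$gene_id %in% tde])) - 2), 0.3)
  # swapping groups negates fold changes and keeps p-values
  de_sw <- nb_differential_expression(ex$counts, b, a, gene_subset = sub)
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-8)
  expect_equal(de_sw$pvalue, de$pvalue, tolerance = 1e-8)

  expect_error(nb_differential_expression(ex$counts, a[1], b),
               class = "proxinet_contract_error")
})

test_that("NB fold changes agree with DESeq2 on the same data", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(seed = 404, n_genes = 60, expr = list(log2fc = 2, n_per_class = 6))
  pl <- generate_peaks_and_loops(cfg, generate_genome(cfg))
  ex <- generate_expression(cfg, pl$truth$genes)
  a <- ex$meta$sample_id[ex$meta$PAX5 == "mutated"]
  b <- ex$meta$sample_id[ex$meta$PAX5 == "wildtype"]
  keep <- filter_expressed(ex$counts, samples = c(a, b))
  de <- nb_differential_expression(ex$counts, a, b, gene_subset = keep)

  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      ex$counts[keep, c(b, a)],
      S4Vectors::DataFrame(group = factor(rep(c("B", "A"), c(length(b), length(a))),
                                          levels = c("B", "A"))),
      ~group)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- as.data.frame(DESeq2::results(dds))
  })
  common <- intersect(rownames(ref), de$gene_id)
  r <- cor(ref[common, "log2FoldChange"], de$log2fc[match(common, de$gene_id)])
  expect_gt(r, 0.98)
  # size factors agree too
  expect_equal(unname(size_factors(ex$counts[, c(b, a)])),
               unname(DESeq2::sizeFactors(dds)), tolerance = 0.02)
})
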
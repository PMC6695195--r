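#' Define a two-group mutation contrast
#'
#' A contrast names, for each group, the required status of one or more
#' lesions (e.g. group A: PAX5 mutated + ETV6-RUNX1 mutated; group B: PAX5
#' mutated only). Samples with unknown status for any lesion referenced by
#' either group are excluded from the comparison.
#'
#' @param a,b named character vectors: lesion -> required status
#'   (`"mutated"` / `"wildtype"`).
#' @param name optional label used in messages.
#' @return list of class `"de_contrast"`.
#' @export
de_contrast <- function(a, b, name = NULL) {
  if (is.null(names(a)) || is.null(names(b))) {
    config_error("contrast groups must be named lesion = status vectors")
  }
  if (is.null(name)) {
    fmt <- function(g) paste(sprintf("%s:%s", names(g), g), collapse = ",")
    name <- sprintf("%s_vs_%s", fmt(a), fmt(b))
  }
  structure(list(a = a, b = b, name = name), class = "de_contrast")
}

#' Select the two sample groups of a contrast
#'
#' Samples whose status is `"unknown"` (or NA) for any lesion referenced
#' by the contrast are excluded before grouping; the two groups are
#' guaranteed disjoint.
#'
#' @param meta sample metadata with `sample_id` and one status column per
#'   lesion.
#' @param contrast a [de_contrast()].
#' @return list with `a` and `b` sample-id vectors and `n_excluded`.
#' @export
select_samples <- function(meta, contrast) {
  stopifnot(inherits(contrast, "de_contrast"))
  lesions <- union(names(contrast$a), names(contrast$b))
  stopifnot_cols(meta, c("sample_id", lesions), "sample metadata")
  known <- rep(TRUE, nrow(meta))
  for (l in lesions) known <- known & !is.na(meta[[l]]) & meta[[l]] != "unknown"
  usable <- meta[known, , drop = FALSE]
  match_group <- function(req) {
    ok <- rep(TRUE, nrow(usable))
    for (l in names(req)) ok <- ok & usable[[l]] == req[[l]]
    usable$sample_id[ok]
  }
  a <- match_group(contrast$a)
  b <- match_group(contrast$b)
  if (length(intersect(a, b))) {
    b <- setdiff(b, a)  # cannot happen when a and b differ on some lesion
  }
  if (!length(a) || !length(b)) {
    contract_error(sprintf("contrast '%s': empty group (A: %d, B: %d samples)",
                           contrast$name, length(a), length(b)))
  }
  list(a = a, b = b, n_excluded = sum(!known))
}

#' Filter genes on expression support
#'
#' A gene is kept when it has at least `min_count` counts in at least
#' `min_samples` of the supplied samples (default: >= 10 counts in >= 2
#' samples), evaluated over the contrast's samples only.
#'
#' @param counts gene x sample count matrix.
#' @param min_count per-sample count threshold (default 10).
#' @param min_samples number of samples required to reach it (default 2).
#' @param samples optional sample-id subset (default: all columns).
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(counts, min_count = 10, min_samples = 2, samples = NULL) {
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  rownames(counts)[rowSums(counts >= min_count) >= min_samples]
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median across genes of the ratio of its
#' count to the gene's geometric mean over samples (genes with any zero
#' count drop out of the reference).
#'
#' @param counts gene x sample count matrix.
#' @return named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) contract_error("no gene has all-positive counts; cannot compute size factors")
  sf <- apply(counts[use, , drop = FALSE], 2, function(col) {
    exp(median(log(col[col > 0]) - log_geo[use][col > 0]))
  })
  sf
}

#' Negative-binomial differential expression between two sample groups
#'
#' A deliberately transparent NB pipeline for bound-gene contrasts:
#' median-of-ratios size factors, per-gene method-of-moments dispersion
#' (pooled within groups, floored), and a Wald test on the group
#' coefficient of a two-group NB log-linear model with the size factors
#' as offsets. No dispersion shrinkage toward a trend, no fold-change
#' shrinkage, no independent filtering. Testing is restricted to
#' `gene_subset` (the bound genes) *before* any testing, and the BH
#' adjustment runs over that tested subset only.
#'
#' @param counts gene x sample integer count matrix.
#' @param group_a,group_b sample-id vectors (>= 2 each). `log2fc > 0`
#'   means higher in group A.
#' @param gene_subset gene ids eligible for testing (default: all rows);
#'   genes with zero total count are dropped with a message.
#' @param dispersion_floor lower bound on the MoM dispersion (default 1e-4).
#' @return data.frame: `gene_id`, `base_mean`, `log2fc`, `lfc_se`, `stat`,
#'   `pvalue`, `padj`.
#' @export
nb_differential_expression <- function(counts, group_a, group_b,
                                       gene_subset = rownames(counts),
                                       dispersion_floor = 1e-4) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    contract_error("need at least 2 samples per group")
  }
  samples <- c(group_a, group_b)
  if (!all(samples %in% colnames(counts))) contract_error("unknown sample ids in groups")
  counts <- counts[, samples, drop = FALSE]
  genes <- intersect(gene_subset, rownames(counts))
  zero <- genes[rowSums(counts[genes, , drop = FALSE]) == 0]
  if (length(zero)) {
    message(sprintf("dropping %d gene(s) with zero total count", length(zero)))
    genes <- setdiff(genes, zero)
  }
  if (!length(genes)) contract_error("no testable genes in gene_subset")

  sf <- size_factors(counts)
  norm <- sweep(counts[genes, , drop = FALSE], 2, sf, "/")
  grp <- factor(ifelse(samples %in% group_a, "A", "B"), levels = c("B", "A"))

  in_a <- grp == "A"
  mom_disp <- function(x) {
    # pooled within-group method of moments: alpha = (var - mu) / mu^2
    est <- vapply(list(x[in_a], x[!in_a]), function(v) {
      m <- mean(v)
      if (m <= 0) return(NA_real_)
      (var(v) - m) / m^2
    }, 0)
    w <- c(sum(in_a), sum(!in_a)) - 1
    ok <- !is.na(est)
    if (!any(ok)) return(dispersion_floor)
    max(sum(est[ok] * w[ok]) / sum(w[ok]), dispersion_floor)
  }
  disp <- apply(norm, 1, mom_disp)

  off <- log(sf)
  fit_one <- function(y, alpha) {
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    fit <- tryCatch(
      suppressWarnings(glm(y ~ grp + offset(off), family = fam)),
      error = function(e) NULL
    )
    if (is.null(fit)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    sm <- summary(fit)$coefficients
    if (!"grpA" %in% rownames(sm)) return(c(NA_real_, NA_real_, NA_real_, NA_real_))
    beta <- sm["grpA", "Estimate"]; se <- sm["grpA", "Std. Error"]
    z <- beta / se
    c(beta / log(2), se / log(2), z, 2 * stats::pnorm(-abs(z)))
  }
  res <- t(vapply(seq_along(genes), function(i) {
    fit_one(counts[genes[i], ], disp[i])
  }, numeric(4)))

  out <- data.frame(
    gene_id = genes,
    base_mean = rowMeans(norm),
    log2fc = res[, 1], lfc_se = res[, 2], stat = res[, 3], pvalue = res[, 4],
    stringsAsFactors = FALSE
  )
  out$padj <- p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' log2 RPKM matrix
#'
#' RPKM = count / (exonic length in kb x library size in millions);
#' returned values are `log2(RPKM + pseudo)`.
#'
#' @param counts gene x sample count matrix.
#' @param lengths named exonic lengths in bp (must cover all genes).
#' @param pseudo pseudo-value added before the log (default 1).
#' @return matrix of the same shape as `counts`.
#' @export
log2_rpkm <- function(counts, lengths, pseudo = 1) {
  if (!all(rownames(counts) %in% names(lengths))) {
    contract_error("lengths must be named for every gene in counts")
  }
  lens <- lengths[rownames(counts)]
  lib <- colSums(counts)
  rpkm <- sweep(counts / (lens / 1e3), 2, lib / 1e6, "/")
  log2(rpkm + pseudo)
}

#' Compare per-sample mean expression of a DE gene list between categories
#'
#' For each sample the mean log2 RPKM over `gene_list` is computed; sample
#' categories are then compared pairwise with a two-sided Mann-Whitney U
#' test -- exact when both groups have fewer than 20 samples and no ties,
#' the tie-corrected normal approximation otherwise.
#'
#' @param log_rpkm matrix from [log2_rpkm()].
#' @param gene_list gene ids to average over.
#' @param categories named list: category label -> sample ids.
#' @return list with `sample_means` (data.frame `sample_id`, `category`,
#'   `mean_log2_rpkm`) and `tests` (data.frame `category_a`, `category_b`,
#'   `U`, `pvalue`).
#' @export
group_mean_comparison <- function(log_rpkm, gene_list, categories) {
  gene_list <- intersect(gene_list, rownames(log_rpkm))
  if (!length(gene_list)) contract_error("no genes from gene_list present in the matrix")
  if (length(categories) < 2) contract_error("need at least two sample categories")
  means <- do.call(rbind, lapply(names(categories), function(cat) {
    ids <- intersect(categories[[cat]], colnames(log_rpkm))
    data.frame(sample_id = ids, category = cat,
               mean_log2_rpkm = colMeans(log_rpkm[gene_list, ids, drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  rownames(means) <- NULL
  pairs <- utils::combn(names(categories), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    x <- means$mean_log2_rpkm[means$category == pairs[1, j]]
    y <- means$mean_log2_rpkm[means$category == pairs[2, j]]
    data.frame(category_a = pairs[1, j], category_b = pairs[2, j],
               U = mann_whitney(x, y)$U, pvalue = mann_whitney(x, y)$pvalue,
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(sample_means = means, tests = tests)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when both samples have n < 20 and there are no ties, otherwise
#' the tie-corrected normal approximation (with continuity correction).
#'
#' @param x,y numeric samples.
#' @return list with `U` and `pvalue`.
#' @export
mann_whitney <- function(x, y) {
  exact <- length(x) < 20 && length(y) < 20 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = !exact))
  list(U = unname(ht$statistic), pvalue = ht$p.value)
}

#' ECDF comparison of responsiveness across gene categories
#'
#' Given a per-gene responsiveness measure (e.g. the expression fold
#' change on factor re-induction) and gene categories (canonically:
#' bound + differentially expressed, bound only, unbound), computes the
#' ECDF per category and the two-sample Kolmogorov-Smirnov D and p-value
#' for every category pair.
#'
#' @param values named numeric vector (names = gene ids).
#' @param categories named list: category -> gene ids. At least two
#'   categories with >= 3 genes each are required.
#' @return list with `ecdf` (named list of ECDF functions), `data` (long
#'   data.frame `gene_id`, `category`, `value`) and `tests` (data.frame
#'   `category_a`, `category_b`, `D`, `pvalue`).
#' @export
responsiveness_ecdf <- function(values, categories) {
  vals <- lapply(categories, function(g) values[intersect(g, names(values))])
  sizes <- lengths(vals)
  if (sum(sizes >= 3) < 2) {
    contract_error("need at least two categories with >= 3 genes each")
  }
  vals <- vals[sizes >= 3]
  dat <- do.call(rbind, lapply(names(vals), function(cat) {
    data.frame(gene_id = names(vals[[cat]]), category = cat,
               value = unname(vals[[cat]]), stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(vals), 2)
  tests <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    ht <- suppressWarnings(ks.test(vals[[pairs[1, j]]], vals[[pairs[2, j]]]))
    data.frame(category_a = pairs[1, j], category_b = pairs[2, j],
               D = unname(ht$statistic), pvalue = ht$p.value,
               stringsAsFactors = FALSE)
  }))
  rownames(tests) <- NULL
  list(ecdf = lapply(vals, ecdf), data = dat, tests = tests)
}

#' Call differentially expressed genes at FDR and fold-change thresholds
#'
#' Up: `padj <= fdr` and `log2fc >= log2(min_fold)`; down analogously with
#' `log2fc <= -log2(min_fold)`. Both boundaries are inclusive.
#'
#' @param de_results output of [nb_differential_expression()].
#' @param fdr adjusted-p threshold (default 0.05).
#' @param min_fold fold-change threshold on the natural scale (default 2).
#' @return list with `up` and `down` gene-id vectors.
#' @export
de_threshold_calls <- function(de_results, fdr = 0.05, min_fold = 2) {
  stopifnot_cols(de_results, c("gene_id", "log2fc", "padj"), "DE results")
  lfc <- log2(min_fold)
  ok <- !is.na(de_results$padj) & de_results$padj <= fdr
  list(up = de_results$gene_id[ok & de_results$log2fc >= lfc],
       down = de_results$gene_id[ok & de_results$log2fc <= -lfc])
}
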
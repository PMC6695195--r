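#' Generate a synthetic gene model table
#'
#' Genes are laid out on a regular grid along each chromosome (spacing of at
#' least 12 interaction bins) with the TSS jittered within one bin, so that
#' TSS-proximity windows of neighbouring genes can never overlap and the
#' downstream annotation ground truth is unambiguous.
#'
#' @param cfg a [sim_config()].
#' @return data.frame with columns `gene_id`, `chrom`, `tss`, `strand`,
#'   `exonic_length`.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  genes_per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  spacing <- floor(cfg$chrom_length / (genes_per_chrom + 1))
  if (spacing < 12 * cfg$bin_size) {
    config_error(sprintf(
      "chromosomes too crowded: gene spacing %d < 12 bins (%d bp); increase chrom_length or n_chroms",
      spacing, 12 * cfg$bin_size))
  }
  withr::with_seed(sim_seed(cfg, "genome"), {
    i <- seq_len(cfg$n_genes)
    chrom_idx <- ((i - 1L) %% cfg$n_chroms) + 1L
    slot <- ((i - 1L) %/% cfg$n_chroms) + 1L
    tss <- slot * spacing + sample.int(cfg$bin_size, cfg$n_genes, replace = TRUE) - 1L
    data.frame(
      gene_id = sprintf("G%05d", i),
      chrom = paste0("chr", chrom_idx),
      tss = tss,
      strand = sample(c("+", "-"), cfg$n_genes, replace = TRUE),
      exonic_length = pmax(200L, round(rlnorm(cfg$n_genes, log(2000), 0.5))),
      stringsAsFactors = FALSE
    )
  })
}

#' Generate TF peak sets, chromatin loops and their ground truth
#'
#' Each gene receives one promoter-proximal regulatory element (within
#' `tss_window` of the TSS) and `n_distal_per_gene` distal elements placed
#' in interaction bins 3-6 bins away from the TSS bin, far (> `tss_window`)
#' from every TSS. Each element draws a bound-TF subset from
#' `cobind_probs` (remaining mass: unbound, no peaks emitted). A bound TF
#' contributes one peak spanning the element with a normalized tag count in
#' `tag_range` (so true peaks survive the default tag filter). Each distal
#' element is joined to its gene's TSS bin by a loop with probability
#' `loop_rate`; loops carry an H3K4me3 mark label and a significance value
#' already below the conventional FDR 0.05 cut (loop significance modelling
#' is upstream of this package).
#'
#' The per-gene true bound-TF set is the union of the TF subsets of its
#' proximal element and of its *looped* distal elements -- exactly what a
#' perfect proximity + loop-mediated annotation can recover; TFs sitting
#' only on unlooped distal elements are genuinely unrecoverable and are
#' excluded from the gene truth (they remain in the element truth).
#'
#' @param cfg a [sim_config()].
#' @param genes output of [generate_genome()].
#' @return list with `peaks` (chrom, start, end, peak_id, tf, tags),
#'   `loops` (BEDPE-like: chrom1, start1, end1, chrom2, start2, end2,
#'   loop_id, mark, significance), and `truth` (list of `elements` and
#'   `genes` data.frames; `genes$bound_tfs` is a [tf_subset_key()]).
#' @export
generate_peaks_and_loops <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_cols(genes, c("gene_id", "chrom", "tss"), "genes")
  bin <- cfg$bin_size
  w <- cfg$element_width
  withr::with_seed(sim_seed(cfg, "peaks"), {
    n_el_per_gene <- 1L + cfg$n_distal_per_gene
    n_el <- nrow(genes) * n_el_per_gene

    gene_idx <- rep(seq_len(nrow(genes)), each = n_el_per_gene)
    is_distal <- rep(c(FALSE, rep(TRUE, cfg$n_distal_per_gene)), nrow(genes))
    tss <- genes$tss[gene_idx]

    # proximal elements: whole element within tss_window of the TSS
    max_off <- cfg$tss_window - w
    offset_prox <- sample.int(2L * max_off + 1L, n_el, replace = TRUE) - max_off - 1L
    start_prox <- tss + offset_prox - (w %/% 2L)

    # distal elements: a bin 3..6 bins from the TSS bin, alternating sides;
    # element sits inside that bin
    tss_bin <- (tss %/% bin) * bin
    offs <- c(3L, -3L, 4L, -4L, 5L, -5L, 6L, -6L)
    slot_in_gene <- rep(seq_len(n_el_per_gene) - 1L, nrow(genes))
    bin_off <- offs[pmax(slot_in_gene, 1L)]
    distal_bin <- tss_bin + bin_off * bin
    start_dist <- distal_bin + sample.int(bin - w, n_el, replace = TRUE) - 1L

    start <- ifelse(is_distal, start_dist, start_prox)
    start <- pmax(start, 0L)
    el <- data.frame(
      element_id = sprintf("E%05d", seq_len(n_el)),
      gene_id = genes$gene_id[gene_idx],
      chrom = genes$chrom[gene_idx],
      start = as.integer(start),
      end = as.integer(start + w),
      class = ifelse(is_distal, "distal", "proximal"),
      stringsAsFactors = FALSE
    )

    # bound-TF subset per element
    keys <- names(cfg$cobind_probs)
    p <- as.numeric(cfg$cobind_probs)
    el$tf_set <- sample(c(keys, ""), n_el, replace = TRUE, prob = c(p, max(0, 1 - sum(p))))

    # loops: distal element bin <-> TSS bin, with probability loop_rate
    el$looped <- el$class == "distal" & runif(n_el) < cfg$loop_rate
    li <- which(el$looped)
    loops <- if (length(li)) {
      a_start <- (el$start[li] %/% bin) * bin
      b_start <- (genes$tss[match(el$gene_id[li], genes$gene_id)] %/% bin) * bin
      swap <- a_start > b_start
      s1 <- ifelse(swap, b_start, a_start)
      s2 <- ifelse(swap, a_start, b_start)
      data.frame(
        chrom1 = el$chrom[li], start1 = s1, end1 = s1 + bin,
        chrom2 = el$chrom[li], start2 = s2, end2 = s2 + bin,
        loop_id = sprintf("L%05d", seq_along(li)),
        mark = "H3K4me3",
        significance = runif(length(li), 0, 0.05),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(chrom1 = character(0), start1 = integer(0), end1 = integer(0),
                 chrom2 = character(0), start2 = integer(0), end2 = integer(0),
                 loop_id = character(0), mark = character(0),
                 significance = numeric(0), stringsAsFactors = FALSE)
    }

    # peaks: one per (element, bound TF)
    tf_lists <- lapply(el$tf_set, tf_subset_labels)
    n_tf <- lengths(tf_lists)
    pk_el <- rep(seq_len(n_el), n_tf)
    peaks <- data.frame(
      chrom = el$chrom[pk_el],
      start = el$start[pk_el],
      end = el$end[pk_el],
      peak_id = sprintf("P%06d", seq_along(pk_el)),
      tf = unlist(tf_lists),
      tags = round(runif(length(pk_el), cfg$tag_range[1], cfg$tag_range[2]), 1),
      element_id = el$element_id[pk_el],
      stringsAsFactors = FALSE
    )

    # per-gene recoverable truth
    contrib <- el$class == "proximal" | el$looped
    gene_tfs <- vapply(genes$gene_id, function(g) {
      tf_subset_key(unlist(tf_lists[el$gene_id == g & contrib]))
    }, "")
    truth_genes <- data.frame(gene_id = genes$gene_id, bound_tfs = unname(gene_tfs),
                              stringsAsFactors = FALSE)

    list(peaks = peaks, loops = loops,
         truth = list(elements = el, genes = truth_genes))
  })
}

#' Generate a BioID spectral-count table with known interactor truth
#'
#' True preys draw Poisson(`lambda_true`) spectral counts in bait runs and
#' Poisson(`lambda_false`) in controls; false preys draw
#' Poisson(`lambda_false`) everywhere. Bait runs follow a biological x
#' technical replicate grid.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (a [spectral_count_table()]) and `truth`
#'   (data.frame: `prey_id`, `is_true`).
#' @export
generate_bioid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  b <- cfg$bioid
  withr::with_seed(sim_seed(cfg, "bioid"), {
    preys <- c(sprintf("T%04d", seq_len(b$n_true_preys)),
               sprintf("F%04d", seq_len(b$n_false_preys)))
    is_true <- rep(c(TRUE, FALSE), c(b$n_true_preys, b$n_false_preys))
    grid <- expand.grid(tech = seq_len(b$n_tech_reps), bio = seq_len(b$n_bio_reps))
    runs <- data.frame(
      run = c(sprintf("bait_b%d_t%d", grid$bio, grid$tech),
              sprintf("ctrl_%d", seq_len(b$n_ctrl_runs))),
      condition = rep(c("bait", "control"), c(nrow(grid), b$n_ctrl_runs)),
      bio_rep = c(grid$bio, rep(NA_integer_, b$n_ctrl_runs)),
      tech_rep = c(grid$tech, rep(NA_integer_, b$n_ctrl_runs)),
      stringsAsFactors = FALSE
    )
    lam <- outer(ifelse(is_true, b$lambda_true, b$lambda_false),
                 as.numeric(runs$condition == "bait"), function(l, bait) {
                   ifelse(bait == 1, l, b$lambda_false)
                 })
    counts <- matrix(rpois(length(lam), lam), nrow = length(preys),
                     dimnames = list(preys, runs$run))
    list(table = spectral_count_table(counts, runs),
         truth = data.frame(prey_id = preys, is_true = is_true, stringsAsFactors = FALSE))
  })
}

#' Generate an RNA-seq count matrix stratified by mutation status
#'
#' Counts are negative binomial with log-normal gene means and per-sample
#' library-depth factors. A fraction `frac_affected` of the genes truly
#' bound by the lesion TF (per the supplied truth) carry a `log2fc` effect
#' (random sign) in the mutated class; unbound genes never do, mirroring
#' the restriction of differential testing to bound gene sets.
#'
#' @param cfg a [sim_config()].
#' @param truth gene truth from [generate_peaks_and_loops()]
#'   (`$truth$genes`), or any data.frame with `gene_id` and `bound_tfs`.
#' @return list with `counts` (gene x sample integer matrix), `meta`
#'   (sample metadata: lesion statuses for PAX5 / IKZF1 / ETV6-RUNX1 and a
#'   cell-type label), `lengths` (named exonic lengths, all 1 kb here), and
#'   `truth` (gene_id, is_de, log2fc).
#' @export
generate_expression <- function(cfg, truth) {
  stopifnot(inherits(cfg, "sim_config"))
  stopifnot_cols(truth, c("gene_id", "bound_tfs"), "truth")
  e <- cfg$expr
  withr::with_seed(sim_seed(cfg, "expr"), {
    genes <- truth$gene_id
    bound <- vapply(truth$bound_tfs, function(k) e$lesion %in% tf_subset_labels(k), TRUE)
    n_de <- round(sum(bound) * e$frac_affected)
    de_genes <- sample(genes[bound], n_de)
    lfc <- setNames(numeric(length(genes)), genes)
    lfc[de_genes] <- e$log2fc * sample(c(1, -1), n_de, replace = TRUE)

    n <- 2L * e$n_per_class
    status <- rep(c("mutated", "wildtype"), each = e$n_per_class)
    depth <- runif(n, e$depth_range[1], e$depth_range[2])
    mu0 <- rlnorm(length(genes), e$mu_log_mean, e$mu_log_sd)
    mu <- outer(seq_along(genes), seq_len(n), function(g, s) {
      mu0[g] * 2^(lfc[g] * (status[s] == "mutated")) * depth[s]
    })
    counts <- if (e$dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / e$dispersion), nrow = length(genes))
    } else {
      matrix(rpois(length(mu), mu), nrow = length(genes))
    }
    dimnames(counts) <- list(genes, sprintf("S%03d", seq_len(n)))

    meta <- data.frame(
      sample_id = colnames(counts),
      PAX5 = if (e$lesion == "PAX5") status else "wildtype",
      IKZF1 = if (e$lesion == "IKZF1") status else "wildtype",
      `ETV6-RUNX1` = if (e$lesion == "ETV6-RUNX1") status else "wildtype",
      cell_type = "tumor",
      check.names = FALSE, stringsAsFactors = FALSE
    )
    if (!e$lesion %in% c("PAX5", "IKZF1", "ETV6-RUNX1")) meta[[e$lesion]] <- status

    list(counts = counts, meta = meta,
         lengths = setNames(rep(1000, length(genes)), genes),
         truth = data.frame(gene_id = genes, is_de = lfc != 0, log2fc = unname(lfc),
                            stringsAsFactors = FALSE))
  })
}

#' Generate a tumor mutation catalogue with co-mutation enrichment
#'
#' Each tumor draws a histology label and a focal-gene mutation with
#' probability `p_focal`. Every other gene mutates independently at
#' `base_rate`; for PXI genes the mutation odds are multiplied by
#' `exp(comut_log_or)` in focally mutated tumors and by
#' `exp(lymphoid_log_or)` in lymphoid tumors, producing the configured
#' co-mutation and lineage enrichments (both 0 log-OR = none).
#'
#' @param cfg a [sim_config()].
#' @param pxi_list character vector of PXI gene symbols (may be empty).
#' @return list with `catalogue` (tumor_id, gene, mutation_type, histology;
#'   tumors with no mutation do not appear) and `truth` (the generating
#'   parameters).
#' @export
generate_mutation_catalogue <- function(cfg, pxi_list) {
  stopifnot(inherits(cfg, "sim_config"))
  m <- cfg$mutation
  pxi_list <- setdiff(unique(as.character(pxi_list)), m$focal_gene)
  withr::with_seed(sim_seed(cfg, "mutation"), {
    background <- sprintf("BG%04d", seq_len(m$n_background_genes))
    genes <- c(pxi_list, background)
    if (!length(genes)) config_error("gene universe is empty")
    tumors <- sprintf("TUM%04d", seq_len(m$n_tumors))
    histology <- sample(c("lymphoid", "myeloid"), m$n_tumors, replace = TRUE,
                        prob = c(m$p_lymphoid, 1 - m$p_lymphoid))
    focal_mut <- runif(m$n_tumors) < m$p_focal

    is_pxi <- genes %in% pxi_list
    logit0 <- qlogis(min(max(m$base_rate, 1e-6), 1 - 1e-6))
    pmat <- outer(seq_len(m$n_tumors), seq_along(genes), function(t, g) {
      plogis(logit0 +
               m$comut_log_or * (is_pxi[g] & focal_mut[t]) +
               m$lymphoid_log_or * (is_pxi[g] & histology[t] == "lymphoid"))
    })
    hit <- matrix(runif(length(pmat)) < pmat, nrow = m$n_tumors)
    idx <- which(hit, arr.ind = TRUE)
    cat_df <- data.frame(
      tumor_id = c(tumors[focal_mut], tumors[idx[, 1]]),
      gene = c(rep(m$focal_gene, sum(focal_mut)), genes[idx[, 2]]),
      stringsAsFactors = FALSE
    )
    cat_df$mutation_type <- sample(c("missense", "nonsense", "frameshift", "deletion"),
                                   nrow(cat_df), replace = TRUE)
    cat_df$histology <- histology[match(cat_df$tumor_id, tumors)]
    cat_df <- cat_df[order(cat_df$tumor_id, cat_df$gene), , drop = FALSE]
    rownames(cat_df) <- NULL
    list(catalogue = cat_df,
         truth = list(focal_gene = m$focal_gene, pxi_list = pxi_list,
                      comut_log_or = m$comut_log_or, histology = setNames(histology, tumors)))
  })
}
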
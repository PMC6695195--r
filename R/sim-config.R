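#' Simulation configuration
#'
#' Builds and validates the configuration object consumed by all synthetic
#' data generators. Defaults describe a small B-cell-progenitor-like study:
#' four transcription factors (the PAX5/EBF1/RUNX1/IKZF1 network) co-binding
#' regulatory elements around TSSs, 5 kb chromatin-interaction bins with a
#' 2.5 kb TSS-proximity window, a BioID screen with 3 biological x 2
#' technical bait replicates, and negative-binomial expression counts whose
#' mutation-dependent effects are restricted to bound genes.
#'
#' @param seed integer seed; every generator is a pure function of
#'   `(seed, cfg)`. Each generator uses its own substream derived from this
#'   seed, so adding a generator never perturbs the others.
#' @param n_genes number of genes to simulate.
#' @param n_chroms number of chromosomes the genes are spread over.
#' @param chrom_length chromosome length in bp.
#' @param bin_size chromatin-interaction bin size in bp (default 5000).
#' @param tss_window TSS-proximity window in bp (default 2500): a feature
#'   within this distance of a TSS counts as promoter-proximal.
#' @param tf_names labels of the simulated transcription factors.
#' @param cobind_probs named numeric vector: probability that a regulatory
#'   element is bound by exactly the TF subset named by the key (keys are
#'   [tf_subset_key()] strings over `tf_names`). Values must lie in `[0,1]`
#'   and sum to at most 1; the remaining mass yields unbound elements.
#' @param loop_rate probability that a distal regulatory element is joined
#'   to its gene's TSS bin by a chromatin loop.
#' @param n_distal_per_gene number of distal regulatory elements per gene
#'   (1..8).
#' @param element_width width of a regulatory element in bp.
#' @param tag_range range of normalized tag counts for emitted peaks; the
#'   lower bound defaults to 15 so true peaks survive the default filter.
#' @param bioid list of BioID parameters: `n_true_preys`, `n_false_preys`,
#'   `lambda_true`, `lambda_false` (Poisson spectral-count rates),
#'   `n_bio_reps`, `n_tech_reps` (bait runs = bio x tech), `n_ctrl_runs`.
#' @param expr list of expression parameters: `n_per_class` samples per
#'   mutation class, `mu_log_mean`/`mu_log_sd` (log-normal gene means),
#'   `dispersion` (NB dispersion; 0 gives Poisson counts), `log2fc`
#'   (effect size on affected genes), `frac_affected` (fraction of bound
#'   genes carrying the effect), `lesion` (TF whose bound genes are
#'   eligible), `depth_range` (per-sample library-depth factors).
#' @param mutation list of mutation-catalogue parameters: `n_tumors`,
#'   `focal_gene`, `p_focal`, `base_rate`, `comut_log_or` (log odds ratio of
#'   PXI mutation given a focal mutation; 0 = no enrichment),
#'   `n_background_genes`, `p_lymphoid`, `lymphoid_log_or`.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       n_chroms = 2L,
                       chrom_length = 1e7,
                       bin_size = 5000L,
                       tss_window = 2500L,
                       tf_names = c("PAX5", "EBF1", "RUNX1", "IKZF1"),
                       cobind_probs = NULL,
                       loop_rate = 0.7,
                       n_distal_per_gene = 1L,
                       element_width = 300L,
                       tag_range = c(15, 60),
                       bioid = list(),
                       expr = list(),
                       mutation = list()) {
  if (is.null(cobind_probs)) cobind_probs <- default_cobind_probs(tf_names)

  bioid <- modifyList(list(
    n_true_preys = 200L, n_false_preys = 800L,
    lambda_true = 20, lambda_false = 0.5,
    n_bio_reps = 3L, n_tech_reps = 2L, n_ctrl_runs = 6L
  ), bioid)
  expr <- modifyList(list(
    n_per_class = 10L, mu_log_mean = log(200), mu_log_sd = 1,
    dispersion = 0.1, log2fc = 2, frac_affected = 0.3,
    lesion = tf_names[[1]], depth_range = c(0.7, 1.3)
  ), expr)
  mutation <- modifyList(list(
    n_tumors = 300L, focal_gene = "PAX5", p_focal = 0.35,
    base_rate = 0.05, comut_log_or = 1.5, n_background_genes = 150L,
    p_lymphoid = 0.6, lymphoid_log_or = 1.0
  ), mutation)

  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_chroms = as.integer(n_chroms), chrom_length = chrom_length,
              bin_size = as.integer(bin_size), tss_window = as.integer(tss_window),
              tf_names = tf_names, cobind_probs = cobind_probs,
              loop_rate = loop_rate, n_distal_per_gene = as.integer(n_distal_per_gene),
              element_width = as.integer(element_width), tag_range = tag_range,
              bioid = bioid, expr = expr, mutation = mutation)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

default_cobind_probs <- function(tf_names) {
  n <- length(tf_names)
  if (n < 1) config_error("tf_names must contain at least one TF")
  probs <- c(setNames(rep(0.25 / n, n), vapply(tf_names, tf_subset_key, "")))
  if (n >= 2) {
    pairs <- utils::combn(tf_names, 2, tf_subset_key)
    probs <- c(probs, setNames(rep(0.25 / length(pairs), length(pairs)), pairs))
  }
  # all-TF class is prominent, mirroring the strong co-binding expected of a
  # functional network
  probs <- c(probs, setNames(0.35, tf_subset_key(tf_names)))
  probs
}

validate_sim_config <- function(cfg) {
  if (!length(cfg$seed) || is.na(cfg$seed)) config_error("seed must be a finite integer")
  if (cfg$n_genes < 1) config_error("n_genes must be >= 1")
  if (cfg$n_chroms < 1) config_error("n_chroms must be >= 1")
  if (cfg$bin_size <= 0) config_error("bin_size must be > 0")
  if (cfg$tss_window <= 0) config_error("tss_window must be > 0")
  if (cfg$tss_window > cfg$bin_size) {
    warning("tss_window exceeds bin_size; TSS-proximal and distal anchors may be conflated",
            call. = FALSE)
  }
  p <- cfg$cobind_probs
  if (any(p < 0 | p > 1)) config_error("cobind_probs must lie in [0, 1]")
  if (sum(p) > 1 + 1e-9) config_error("cobind_probs must sum to at most 1")
  bad <- setdiff(unlist(lapply(names(p), tf_subset_labels)), cfg$tf_names)
  if (length(bad)) config_error(sprintf("cobind_probs names unknown TFs: %s", paste(bad, collapse = ", ")))
  if (cfg$loop_rate < 0 || cfg$loop_rate > 1) config_error("loop_rate must lie in [0, 1]")
  if (cfg$n_distal_per_gene < 0 || cfg$n_distal_per_gene > 8) {
    config_error("n_distal_per_gene must be in 0..8")
  }
  if (cfg$element_width <= 0 || cfg$element_width >= cfg$tss_window) {
    config_error("element_width must be in (0, tss_window)")
  }
  b <- cfg$bioid
  if (b$lambda_false < 0 || b$lambda_true < 0) config_error("BioID Poisson rates must be >= 0")
  if (b$lambda_true < b$lambda_false) config_error("lambda_true must be >= lambda_false")
  if (b$n_ctrl_runs < 1) config_error("at least one control run is required")
  if (b$n_bio_reps < 1 || b$n_tech_reps < 1) config_error("bait replicate counts must be >= 1")
  e <- cfg$expr
  if (e$n_per_class < 2) config_error("each mutation class needs at least 2 samples")
  if (e$dispersion < 0) config_error("NB dispersion must be >= 0")
  if (e$frac_affected < 0 || e$frac_affected > 1) config_error("frac_affected must lie in [0, 1]")
  if (!(e$lesion %in% cfg$tf_names)) config_error("expr$lesion must be one of tf_names")
  m <- cfg$mutation
  if (m$n_tumors < 1) config_error("n_tumors must be >= 1")
  if (m$p_focal < 0 || m$p_focal > 1 || m$base_rate < 0 || m$base_rate > 1 ||
      m$p_lymphoid < 0 || m$p_lymphoid > 1) {
    config_error("mutation probabilities must lie in [0, 1]")
  }
  cfg
}

# fixed substream offsets: one per generator
sim_seed <- function(cfg, stream) {
  offset <- c(genome = 11L, peaks = 23L, bioid = 37L, expr = 53L, mutation = 71L)[[stream]]
  (cfg$seed %% 2000000000L) + offset
}
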
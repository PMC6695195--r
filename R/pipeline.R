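#' Build a pipeline configuration
#'
#' A single configuration drives the end-to-end run: either all inputs are
#' generated synthetically (`simulate = TRUE`, the one-command demo) or
#' paths to existing BED/BEDPE/TSV inputs are supplied. Stage parameters
#' default to the conventional values: control collapse k = 2, BFDR 0.02 /
#' score 0.80 PXI selection, >= 15 normalized tags, 2.5 kb TSS window,
#' 5 kb bins, DE calls at FDR 0.05 and fold >= 2, expression support >= 10
#' counts in >= 2 samples.
#'
#' @param seed integer seed for the simulated inputs.
#' @param simulate generate all inputs synthetically.
#' @param sim list of [sim_config()] arguments (used when `simulate`).
#' @param inputs named list of file paths (`genes`, `peaks`, `loops`,
#'   `bioid_counts`, `bioid_runs`, `expr_counts`, `sample_meta`,
#'   `mutations`) when `simulate = FALSE`.
#' @param params named list overriding stage parameters (see Details).
#' @param stages character vector of stages to run, in dependency order;
#'   any of `"bioid"`, `"peaks"`, `"loops"`, `"cobind"`, `"de"`, `"comut"`.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L, simulate = TRUE, sim = list(),
                            inputs = list(), params = list(),
                            stages = c("bioid", "peaks", "loops", "cobind", "de", "comut")) {
  params <- modifyList(list(
    collapse_k = 2L, bfdr_max = 0.02, score_min = 0.80, select_rule = "or",
    min_tags = 15, tss_window = 2500L, bin_size = 5000L,
    fdr = 0.05, min_fold = 2, min_count = 10L, min_samples = 2L
  ), params)
  bad <- setdiff(stages, c("bioid", "peaks", "loops", "cobind", "de", "comut"))
  if (length(bad)) config_error(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  cfg <- list(seed = as.integer(seed), simulate = isTRUE(simulate), sim = sim,
              inputs = inputs, params = params, stages = stages)
  class(cfg) <- "pipeline_config"
  if (!cfg$simulate) {
    needed <- c("genes", "peaks", "loops", "bioid_counts", "bioid_runs",
                "expr_counts", "sample_meta", "mutations")
    for (nm in intersect(needed, needed_inputs(stages))) {
      path <- cfg$inputs[[nm]]
      if (is.null(path)) config_error(sprintf("inputs$%s is required for the selected stages", nm))
      if (!file.exists(path)) config_error(sprintf("input file not found: inputs$%s = %s", nm, path))
    }
  }
  cfg
}

needed_inputs <- function(stages) {
  need <- character(0)
  if ("bioid" %in% stages) need <- c(need, "bioid_counts", "bioid_runs")
  if (any(c("peaks", "loops", "cobind", "de") %in% stages)) need <- c(need, "genes", "peaks")
  if (any(c("loops", "cobind", "de") %in% stages)) need <- c(need, "loops")
  if ("de" %in% stages) need <- c(need, "expr_counts", "sample_meta")
  if ("comut" %in% stages) need <- c(need, "mutations")
  unique(need)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path configuration file; format chosen by extension
#'   (`.yml`/`.yaml` vs `.json`).
#' @return a validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw[intersect(names(raw),
    c("seed", "simulate", "sim", "inputs", "params", "stages"))])
}

#' Run the full pipeline into a run directory
#'
#' Executes the stages in dependency order (bioid -> peaks -> loops ->
#' cobind -> de -> comut; each skippable via the config), writing every
#' stage output as TSV/BED/BEDPE under `out_dir` plus a machine-readable
#' `manifest.json` recording the package version, parameters, input
#' checksums, per-stage record counts in/out, and output checksums. A
#' rerun with the same config and inputs is bit-identical. On a stage
#' failure, partial outputs are kept and a `failed/<stage>` marker is
#' written before the error (naming the stage) is re-thrown.
#'
#' When inputs are simulated, ground truth is written alongside and a
#' truth-recovery report (co-bound gene sets vs truth, BioID selection vs
#' truth) is emitted.
#'
#' @param config a [pipeline_config()] or a path to one (YAML/JSON).
#' @param out_dir run directory (created; must be empty or absent unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite) {
    config_error(sprintf("out_dir '%s' is not empty (use overwrite = TRUE)", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  p <- config$params
  manifest <- list(
    package = "proxinet",
    version = as.character(utils::packageVersion("proxinet")),
    seed = config$seed, simulate = config$simulate,
    parameters = p, stages = config$stages, counts = list()
  )
  results <- list()
  log_counts <- function(stage, ...) {
    manifest$counts[[stage]] <<- c(manifest$counts[[stage]], list(...))
  }
  run_stage <- function(stage, fun) {
    if (!stage %in% c(config$stages, "simulate", "load")) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      dir.create(file.path(out_dir, "failed"), showWarnings = FALSE)
      writeLines(conditionMessage(e), file.path(out_dir, "failed", stage))
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)), call. = FALSE)
    })
  }

  # ---- inputs -------------------------------------------------------------
  truth <- NULL
  run_stage("simulate", function() {
    if (config$simulate) {
      sim <- do.call(sim_config, modifyList(list(seed = config$seed), config$sim))
      genes <- generate_genome(sim)
      pl <- generate_peaks_and_loops(sim, genes)
      bio <- generate_bioid(sim)
      expr <- generate_expression(sim, pl$truth$genes)
      mut <- generate_mutation_catalogue(sim, bio$truth$prey_id[bio$truth$is_true])
      write_tsv(genes, file.path(in_dir, "genes.tsv"))
      write_peaks_bed(pl$peaks, file.path(in_dir, "peaks.bed"))
      write_loops_bedpe(pl$loops, file.path(in_dir, "loops.bedpe"))
      write_tsv(data.frame(prey_id = rownames(bio$table$counts), bio$table$counts,
                           check.names = FALSE), file.path(in_dir, "bioid_counts.tsv"))
      write_tsv(bio$table$runs, file.path(in_dir, "bioid_runs.tsv"))
      write_tsv(data.frame(gene_id = rownames(expr$counts), expr$counts,
                           check.names = FALSE), file.path(in_dir, "expr_counts.tsv"))
      write_tsv(expr$meta, file.path(in_dir, "sample_meta.tsv"))
      write_tsv(mut$catalogue, file.path(in_dir, "mutations.tsv"))
      write_tsv(pl$truth$elements, file.path(in_dir, "truth_elements.tsv"))
      write_tsv(pl$truth$genes, file.path(in_dir, "truth_genes.tsv"))
      write_tsv(bio$truth, file.path(in_dir, "truth_preys.tsv"))
      write_tsv(expr$truth, file.path(in_dir, "truth_expression.tsv"))
      truth <<- list(elements = pl$truth$elements, genes = pl$truth$genes,
                     preys = bio$truth, expression = expr$truth, sim = sim)
      results$sim <<- sim
    } else {
      for (nm in needed_inputs(config$stages)) {
        file.copy(config$inputs[[nm]], file.path(in_dir, basename(config$inputs[[nm]])))
      }
    }
  })
  paths <- if (config$simulate) {
    list(genes = file.path(in_dir, "genes.tsv"), peaks = file.path(in_dir, "peaks.bed"),
         loops = file.path(in_dir, "loops.bedpe"),
         bioid_counts = file.path(in_dir, "bioid_counts.tsv"),
         bioid_runs = file.path(in_dir, "bioid_runs.tsv"),
         expr_counts = file.path(in_dir, "expr_counts.tsv"),
         sample_meta = file.path(in_dir, "sample_meta.tsv"),
         mutations = file.path(in_dir, "mutations.tsv"))
  } else config$inputs
  manifest$input_md5 <- as.list(tools::md5sum(unlist(paths[needed_inputs(config$stages)])))

  # ---- bioid --------------------------------------------------------------
  run_stage("bioid", function() {
    counts <- read_tsv(paths$bioid_counts)
    mat <- as.matrix(counts[, -1, drop = FALSE]); rownames(mat) <- counts[[1]]
    runs <- read_tsv(paths$bioid_runs)
    tab <- spectral_count_table(mat, runs)
    collapsed <- collapse_controls(tab, k = p$collapse_k)
    scores <- bayesian_fdr(score_interactions(collapsed))
    sel <- select_pxis(scores, bfdr_max = p$bfdr_max, score_min = p$score_min,
                       rule = p$select_rule)
    scores$selected <- scores$prey_id %in% sel$prey_id
    write_tsv(scores, file.path(out_dir, "pxi_scores.tsv"))
    log_counts("bioid", n_preys = nrow(scores), n_selected = nrow(sel))
    results$pxi_scores <<- scores
    results$pxis <<- sel$prey_id
  })

  # ---- peaks --------------------------------------------------------------
  run_stage("peaks", function() {
    genes <- read_tsv(paths$genes)
    peaks <- read_peaks(paths$peaks, dialect = "bed")
    # the 6-col BED written here stores the TF label in column 6
    raw <- read.table(paths$peaks, sep = "\t", stringsAsFactors = FALSE)
    if (ncol(raw) >= 6) peaks$tf <- raw[[6]]
    filtered <- filter_peaks(peaks, p$min_tags)
    merged <- merge_peak_sets(filtered)
    combos <- combination_counts(merged)
    prox <- annotate_proximal(filtered, genes, window = p$tss_window)
    write_tsv(merged, file.path(out_dir, "merged_peaks.tsv"))
    write_tsv(combos, file.path(out_dir, "peak_combination_counts.tsv"))
    write_tsv(prox, file.path(out_dir, "proximal_assignments.tsv"))
    log_counts("peaks", n_in = nrow(peaks), n_filtered = nrow(filtered),
               n_merged = nrow(merged), n_proximal_assignments = nrow(prox))
    results$genes <<- genes
    results$peaks <<- filtered
    results$merged_peaks <<- merged
    results$proximal <<- prox
  })

  # ---- loops --------------------------------------------------------------
  run_stage("loops", function() {
    loops <- merge_loops(read_loops_bedpe(paths$loops), bin_size = p$bin_size)
    anchors <- classify_anchors(loops, results$genes, tss_window = p$tss_window)
    combos <- anchor_tf_combinations(loops, results$peaks)
    parts <- split_peaks_by_tss(results$peaks, results$genes, window = p$tss_window)
    distal <- assign_distal_peaks(parts$distal, loops, anchors)
    write_loops_bedpe(loops, file.path(out_dir, "merged_loops.bedpe"))
    write_tsv(anchors, file.path(out_dir, "anchor_classes.tsv"))
    write_tsv(combos$counts, file.path(out_dir, "anchor_tf_combinations.tsv"))
    write_tsv(distal$assignments, file.path(out_dir, "loop_assignments.tsv"))
    log_counts("loops", n_loops = nrow(loops), n_anchors = nrow(anchors),
               n_loops_excluded = combos$n_excluded,
               n_distal_peaks = nrow(parts$distal),
               n_distal_assigned = length(unique(distal$assignments$peak_id)),
               n_distal_discarded = length(distal$discarded))
    results$loops <<- loops
    results$loop_assignments <<- distal$assignments
    results$discarded_peaks <<- distal$discarded
  })

  # ---- cobind -------------------------------------------------------------
  run_stage("cobind", function() {
    cb <- cobound_genes(results$proximal, results$loop_assignments)
    write_tsv(cb$genes, file.path(out_dir, "cobound_genes.tsv"))
    log_counts("cobind", n_bound_genes = nrow(cb$genes))
    results$cobound <<- cb
    if (!is.null(truth)) {
      tr <- truth$genes
      got <- setNames(cb$genes$tf_set, cb$genes$gene_id)
      want <- setNames(tr$bound_tfs, tr$gene_id)
      all_g <- union(names(got), names(want))
      cmp <- data.frame(gene_id = all_g,
                        truth = ifelse(is.na(want[all_g]), "", want[all_g]),
                        recovered = ifelse(is.na(got[all_g]), "", got[all_g]),
                        stringsAsFactors = FALSE)
      cmp$match <- cmp$truth == cmp$recovered
      write_tsv(cmp, file.path(out_dir, "truth_recovery.tsv"))
      log_counts("cobind", n_truth_mismatches = sum(!cmp$match))
      results$truth_recovery <<- cmp
    }
  })

  # ---- de -----------------------------------------------------------------
  run_stage("de", function() {
    counts <- read_tsv(paths$expr_counts)
    mat <- as.matrix(counts[, -1, drop = FALSE]); rownames(mat) <- counts[[1]]
    meta <- read_tsv(paths$sample_meta)
    lesion <- if (config$simulate) results$sim$expr$lesion else "PAX5"
    contrast <- de_contrast(setNames("mutated", lesion), setNames("wildtype", lesion),
                            name = sprintf("%sM_vs_%sWT", lesion, lesion))
    grp <- select_samples(meta, contrast)
    expressed <- filter_expressed(mat, min_count = p$min_count,
                                  min_samples = p$min_samples, samples = c(grp$a, grp$b))
    bound <- results$cobound$genes$gene_id[
      vapply(results$cobound$genes$tf_set,
             function(k) lesion %in% tf_subset_labels(k), TRUE)]
    de <- nb_differential_expression(mat, grp$a, grp$b,
                                     gene_subset = intersect(expressed, bound))
    calls <- de_threshold_calls(de, fdr = p$fdr, min_fold = p$min_fold)
    de$call <- ifelse(de$gene_id %in% calls$up, "up",
                      ifelse(de$gene_id %in% calls$down, "down", "ns"))
    write_tsv(de, file.path(out_dir, "de_results.tsv"))
    log_counts("de", contrast = contrast$name, n_group_a = length(grp$a),
               n_group_b = length(grp$b), n_excluded_samples = grp$n_excluded,
               n_expressed = length(expressed), n_bound_tested = nrow(de),
               n_up = length(calls$up), n_down = length(calls$down))
    de_genes <- c(calls$up, calls$down)
    if (length(de_genes) >= 1) {
      lengths_bp <- setNames(rep(1000, nrow(mat)), rownames(mat))
      lr <- log2_rpkm(mat, lengths_bp)
      gm <- group_mean_comparison(lr, de_genes,
                                  list(mutated = grp$a, wildtype = grp$b))
      write_tsv(gm$sample_means, file.path(out_dir, "de_sample_means.tsv"))
      write_tsv(gm$tests, file.path(out_dir, "de_group_tests.tsv"))
      results$group_comparison <<- gm
    }
    results$de <<- de
    results$de_calls <<- calls
  })

  # ---- comut --------------------------------------------------------------
  run_stage("comut", function() {
    cat_df <- read_tsv(paths$mutations)
    pxi <- results$pxis %||% character(0)
    fr <- pxi_mutation_fractions(cat_df, pxi)
    write_tsv(data.frame(metric = c("frac_mutated_genes_pxi", "frac_pxis_mutated"),
                         value = c(fr$frac_mutated_genes_pxi, fr$frac_pxis_mutated),
                         numerator = c(fr$n_mutated_pxis, fr$n_mutated_pxis),
                         denominator = c(fr$n_mutated_genes, fr$n_pxis)),
              file.path(out_dir, "pxi_mutation_fractions.tsv"))
    focal <- if (config$simulate) results$sim$mutation$focal_gene else "PAX5"
    if (focal %in% cat_df$gene) {
      cm <- comutation_matrix(cat_df, focal, pxi)
      mat_df <- data.frame(tumor_id = rownames(cm$matrix),
                           as.data.frame(cm$matrix * 1L), check.names = FALSE)
      write_tsv(mat_df, file.path(out_dir, "comutation_matrix.tsv"))
      log_counts("comut", n_focal_tumors = cm$n_focal_tumors,
                 n_comut_tumors = nrow(cm$matrix))
      results$comutation <<- cm
    }
    if ("histology" %in% names(cat_df)) {
      hb <- histology_breakdown(cat_df, pxi)
      write_tsv(hb, file.path(out_dir, "histology_breakdown.tsv"))
      results$histology <<- hb
    }
    results$pxi_fractions <<- fr
  })

  out_files <- setdiff(list.files(out_dir, recursive = TRUE, full.names = TRUE),
                       file.path(out_dir, "manifest.json"))
  manifest$output_md5 <- as.list(tools::md5sum(out_files))
  names(manifest$output_md5) <- sub(paste0("^", out_dir, "/?"), "",
                                    names(manifest$output_md5))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
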
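#' Spectral-count table constructor
#'
#' Container for a BioID prey x run spectral-count matrix plus run metadata.
#'
#' @param counts non-negative integer matrix, rows = preys, columns = runs.
#' @param runs data.frame with columns `run`, `condition` (`"bait"` or
#'   `"control"`), `bio_rep`, `tech_rep` (replicate ids; NA for controls).
#' @return list of class `"spectral_count_table"` with elements `counts`
#'   and `runs`.
#' @export
spectral_count_table <- function(counts, runs) {
  stopifnot_cols(runs, c("run", "condition", "bio_rep", "tech_rep"), "runs")
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("prey_%d", seq_len(nrow(counts)))
  if (!identical(colnames(counts), as.character(runs$run))) {
    counts <- counts[, as.character(runs$run), drop = FALSE]
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    contract_error("spectral counts must be non-negative integers")
  }
  if (!any(runs$condition == "bait") || !any(runs$condition == "control")) {
    contract_error("need at least one bait and one control run")
  }
  structure(list(counts = counts, runs = runs), class = "spectral_count_table")
}

#' @export
print.spectral_count_table <- function(x, ...) {
  cat(sprintf("spectral_count_table: %d preys, %d bait runs, %d control runs\n",
              nrow(x$counts), sum(x$runs$condition == "bait"),
              sum(x$runs$condition == "control")))
  invisible(x)
}

#' Collapse control runs to the k highest counts per prey
#'
#' For each prey only the `k` largest control spectral counts are retained
#' (the standard conservative treatment of pooled negative controls before
#' two-component scoring); bait runs are untouched. With fewer than `k`
#' control runs all controls are kept and a warning is issued.
#'
#' Because the top-k set differs between preys, the collapsed controls are
#' re-labelled `ctrl_top1..ctrl_topk` (rank columns, not original runs).
#'
#' @param x a [spectral_count_table()].
#' @param k number of control values to keep per prey (default 2).
#' @return a collapsed [spectral_count_table()].
#' @export
collapse_controls <- function(x, k = 2L) {
  stopifnot(inherits(x, "spectral_count_table"))
  if (k <= 0) config_error("k must be a positive integer")
  ctrl <- x$runs$condition == "control"
  n_ctrl <- sum(ctrl)
  keep <- min(k, n_ctrl)
  if (n_ctrl < k) {
    warning(sprintf("only %d control run(s) available; keeping all (k = %d)", n_ctrl, k),
            call. = FALSE)
  }
  top <- t(apply(x$counts[, ctrl, drop = FALSE], 1, function(v) {
    sort(v, decreasing = TRUE)[seq_len(keep)]
  }))
  if (keep == 1L) top <- matrix(top, ncol = 1L)
  colnames(top) <- sprintf("ctrl_top%d", seq_len(keep))
  counts <- cbind(x$counts[, !ctrl, drop = FALSE], top)
  runs <- rbind(
    x$runs[!ctrl, , drop = FALSE],
    data.frame(run = colnames(top), condition = "control",
               bio_rep = NA_integer_, tech_rep = NA_integer_,
               stringsAsFactors = FALSE)
  )
  spectral_count_table(counts, runs)
}

#' Score candidate proximity interactors from spectral counts
#'
#' A documented simplified two-component Poisson scorer in the SAINT
#' family. Per prey, the false-interaction rate is the moderated control
#' mean plus a pseudocount,
#' `lambda_false = (sum(control counts) + m * overall control mean) /
#' (n_controls + m) + pseudocount`, and the true rate is
#' `lambda_true = max(mean(bait counts), lambda_false + delta)`. For each
#' bait run with count x the posterior probability of a true interaction
#' under a uniform prior is
#' `P(x | lambda_true) / (P(x | lambda_true) + P(x | lambda_false))`.
#' Probabilities are averaged over technical replicates within each
#' biological replicate first; the prey score (AvgP) is the mean over
#' biological replicates.
#'
#' The `m` pseudo-observations at the experiment-wide control mean are an
#' empirical-Bayes guard: with only a couple of retained control values
#' per prey, a background prey whose controls are all zero by chance would
#' otherwise get a near-zero false rate and a spuriously confident score,
#' which makes the downstream Bayesian FDR anticonservative. `m = 0`
#' recovers the unmoderated per-prey control mean.
#'
#' @param x a (typically control-collapsed) [spectral_count_table()].
#' @param pseudocount added to the moderated control mean so all-zero
#'   control experiments do not produce degenerate likelihood ratios
#'   (default 0.1).
#' @param delta floor separation of `lambda_true` above `lambda_false`
#'   (default 0.1).
#' @param m number of pseudo-observations at the experiment-wide control
#'   mean (default 1).
#' @return data.frame of class `"interactor_scores"`: `prey_id`,
#'   `lambda_false`, `lambda_true`, `score` in `[0, 1]`, plus a
#'   `"replicate_probs"` attribute (prey x biological replicate matrix).
#' @export
score_interactions <- function(x, pseudocount = 0.1, delta = 0.1, m = 1) {
  stopifnot(inherits(x, "spectral_count_table"))
  if (pseudocount < 0 || delta <= 0 || m < 0) {
    config_error("pseudocount and m must be >= 0 and delta > 0")
  }
  if (nrow(x$counts) == 0) {
    res <- data.frame(prey_id = character(0), lambda_false = numeric(0),
                      lambda_true = numeric(0), score = numeric(0))
    class(res) <- c("interactor_scores", "data.frame")
    return(res)
  }
  bait <- x$runs$condition == "bait"
  bait_counts <- x$counts[, bait, drop = FALSE]
  ctrl_counts <- x$counts[, !bait, drop = FALSE]
  bio <- x$runs$bio_rep[bait]

  overall_ctrl <- mean(ctrl_counts)
  lam_false <- (rowSums(ctrl_counts) + m * overall_ctrl) / (ncol(ctrl_counts) + m) + pseudocount
  lam_true <- pmax(rowMeans(bait_counts), lam_false + delta)

  # P(true | x) per bait run, via log-likelihood difference
  ll_t <- dpois(bait_counts, matrix(lam_true, nrow(bait_counts), ncol(bait_counts)), log = TRUE)
  ll_f <- dpois(bait_counts, matrix(lam_false, nrow(bait_counts), ncol(bait_counts)), log = TRUE)
  p_run <- 1 / (1 + exp(ll_f - ll_t))

  bio_levels <- sort(unique(bio))
  rep_probs <- vapply(bio_levels, function(b) {
    rowMeans(p_run[, bio == b, drop = FALSE])
  }, numeric(nrow(p_run)))
  if (is.null(dim(rep_probs))) rep_probs <- matrix(rep_probs, ncol = length(bio_levels))
  colnames(rep_probs) <- paste0("bio_rep", bio_levels)

  res <- data.frame(
    prey_id = rownames(x$counts),
    lambda_false = unname(lam_false),
    lambda_true = unname(lam_true),
    score = unname(rowMeans(rep_probs)),
    stringsAsFactors = FALSE
  )
  attr(res, "replicate_probs") <- rep_probs
  class(res) <- c("interactor_scores", "data.frame")
  res
}

#' Bayesian FDR over a ranked interactor list
#'
#' `BFDR(k)` is the running mean of `(1 - score)` over the k top-scoring
#' preys, i.e. the expected false-discovery proportion of the list cut at
#' rank k. Tied scores share the worst (largest) BFDR of their tied block,
#' so the cut never splits a tie. Row order of the input is preserved.
#'
#' @param scores output of [score_interactions()] (needs `prey_id`, `score`).
#' @return `scores` with a `bfdr` column added.
#' @export
bayesian_fdr <- function(scores) {
  stopifnot_cols(scores, c("prey_id", "score"), "scores")
  if (nrow(scores) == 0) {
    scores$bfdr <- numeric(0)
    return(scores)
  }
  ord <- order(scores$score, decreasing = TRUE)
  run_mean <- cumsum(1 - scores$score[ord]) / seq_along(ord)
  # ties (equal scores are adjacent after sorting) share the block's max
  run_mean <- stats::ave(run_mean, scores$score[ord], FUN = max)
  scores$bfdr <- NA_real_
  scores$bfdr[ord] <- run_mean
  scores
}

#' Select high-confidence proximity interactors (PXIs)
#'
#' The conventional cut is BFDR <= 0.02, which on well-behaved screens
#' corresponds to a score around 0.80; both thresholds are exposed and can
#' be combined as a disjunction (default, either suffices) or conjunction.
#'
#' @param scores output of [bayesian_fdr()].
#' @param bfdr_max BFDR threshold (default 0.02).
#' @param score_min score threshold (default 0.80).
#' @param rule `"or"` (default) or `"and"`.
#' @return `scores` restricted to selected preys, sorted by score
#'   descending, with a `selected` column (all TRUE).
#' @export
select_pxis <- function(scores, bfdr_max = 0.02, score_min = 0.80, rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot_cols(scores, c("prey_id", "score", "bfdr"), "scores")
  keep <- if (rule == "or") {
    scores$bfdr <= bfdr_max | scores$score >= score_min
  } else {
    scores$bfdr <= bfdr_max & scores$score >= score_min
  }
  out <- scores[keep, , drop = FALSE]
  out <- out[order(out$score, decreasing = TRUE), , drop = FALSE]
  out$selected <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}
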
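# Brute-force reference implementations and random-instance generators.
# These are deliberately naive (all-pairs, repeated-pass closures) so they
# stay independent of the interval machinery used by the package.

overlaps0 <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# connected components of an adjacency matrix by repeated label passes
brute_components <- function(adj) {
  n <- nrow(adj)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb)) {
        m <- min(comp[c(i, nb)])
        if (any(comp[c(i, nb)] != m)) {
          comp[c(i, nb)] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}

oracle_merge_peaks <- function(peaks) {
  n <- nrow(peaks)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    overlaps0(peaks$chrom[i], peaks$start[i], peaks$end[i],
              peaks$chrom[j], peaks$start[j], peaks$end[j]) & i != j
  })
  comp <- brute_components(adj)
  do.call(rbind, lapply(split(seq_len(n), comp), function(i) {
    data.frame(chrom = peaks$chrom[i[1]], start = min(peaks$start[i]),
               end = max(peaks$end[i]), members = tf_subset_key(peaks$tf[i]),
               n_peaks = length(i), stringsAsFactors = FALSE)
  }))
}

oracle_merge_loops <- function(loops, bin_size) {
  n <- nrow(loops)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    loops$chrom1[i] == loops$chrom1[j] & loops$chrom2[i] == loops$chrom2[j] &
      abs(loops$start1[i] - loops$start1[j]) <= bin_size &
      abs(loops$start2[i] - loops$start2[j]) <= bin_size & i != j
  })
  comp <- brute_components(adj)
  do.call(rbind, lapply(split(seq_len(n), comp), function(i) {
    data.frame(chrom1 = loops$chrom1[i[1]], start1 = min(loops$start1[i]),
               end1 = max(loops$end1[i]), chrom2 = loops$chrom2[i[1]],
               start2 = min(loops$start2[i]), end2 = max(loops$end2[i]),
               n_members = length(i), stringsAsFactors = FALSE)
  }))
}

oracle_anchor_sets <- function(loop, peaks) {
  at <- function(chrom, s, e) {
    hit <- overlaps0(peaks$chrom, peaks$start, peaks$end, chrom, s, e)
    tf_subset_key(peaks$tf[hit])
  }
  c(at(loop$chrom1, loop$start1, loop$end1), at(loop$chrom2, loop$start2, loop$end2))
}

# distance from half-open interval to point, measured to the boundary
oracle_dist <- function(s, e, p) max(s - p, p - e, 0)

random_peak_instance <- function(n, tfs = c("A", "B", "C"), span = 2000) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    start = start,
    end = start + sample.int(150, n, replace = TRUE),
    peak_id = sprintf("p%03d", seq_len(n)),
    tf = sample(tfs, n, replace = TRUE),
    tags = runif(n, 0, 40),
    stringsAsFactors = FALSE
  )
}

random_loop_instance <- function(n, bin = 1000, span_bins = 30) {
  s1 <- sample.int(span_bins, n, replace = TRUE) * bin
  s2 <- s1 + (2 + sample.int(span_bins, n, replace = TRUE)) * bin
  data.frame(
    chrom1 = "chr1", start1 = s1, end1 = s1 + bin,
    chrom2 = "chr1", start2 = s2, end2 = s2 + bin,
    loop_id = sprintf("l%03d", seq_len(n)),
    stringsAsFactors = FALSE
  )
}

# small spectral-count table from explicit bait/control vectors (one prey)
sct_one_prey <- function(bait, ctrl, prey = "P1", n_bio = length(bait), n_tech = 1) {
  counts <- matrix(c(bait, ctrl), nrow = 1,
                   dimnames = list(prey, c(sprintf("bait_%d", seq_along(bait)),
                                           sprintf("ctrl_%d", seq_along(ctrl)))))
  runs <- data.frame(
    run = colnames(counts),
    condition = rep(c("bait", "control"), c(length(bait), length(ctrl))),
    bio_rep = c(seq_along(bait), rep(NA, length(ctrl))),
    tech_rep = c(rep(1L, length(bait)), rep(NA, length(ctrl))),
    stringsAsFactors = FALSE
  )
  spectral_count_table(counts, runs)
}

# direct single-prey evaluation of the scoring model (independent arithmetic)
oracle_score_one <- function(bait, ctrl, bio = seq_along(bait),
                             pseudocount = 0.1, delta = 0.1, m = 1,
                             overall_ctrl = mean(ctrl)) {
  lf <- (sum(ctrl) + m * overall_ctrl) / (length(ctrl) + m) + pseudocount
  lt <- max(mean(bait), lf + delta)
  p <- vapply(bait, function(x) {
    a <- exp(-lt) * lt^x / factorial(x)
    b <- exp(-lf) * lf^x / factorial(x)
    a / (a + b)
  }, 0)
  mean(vapply(unique(bio), function(bb) mean(p[bio == bb]), 0))
}
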
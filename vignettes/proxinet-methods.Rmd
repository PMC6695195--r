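---
title: "proxinet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proxinet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

proxinet links a transcription factor's BioID proximity interactome to the
regulatory network it shares with its partner factors. The pipeline has five
analytical stages — interactor scoring, peak-set algebra, loop-mediated
target-gene annotation, mutation-stratified differential expression of bound
gene sets, and tumor co-mutation statistics — plus a synthetic-data module
that generates every input with known ground truth. This vignette explains
the models, the parameters that matter, and the design decisions behind
them.

## Interactor scoring from spectral counts

BioID spectral counts for a prey protein are modelled as a two-component
Poisson mixture: rate $\lambda_{true}$ in bait runs when the prey is a real
proximity interactor, rate $\lambda_{false}$ (ambient background, shared
with negative-control runs) otherwise. Per prey:

* $\lambda_{false} = \dfrac{\sum_j c_j + m\,\bar c}{n_c + m} + c_0$, where
  $c_j$ are the prey's retained control counts, $\bar c$ the experiment-wide
  mean control count, $m = 1$ pseudo-observation and $c_0 = 0.1$ a
  pseudocount;
* $\lambda_{true} = \max(\text{mean bait count},\ \lambda_{false} + \delta)$
  with floor $\delta = 0.1$;
* for each bait run with count $x$, the posterior probability of a true
  interaction under a uniform prior is
  $p = \frac{P(x \mid \lambda_{true})}{P(x \mid \lambda_{true}) + P(x \mid \lambda_{false})}$;
* probabilities are averaged over technical replicates within each
  biological replicate, then over biological replicates, giving the prey
  score (an AvgP).

Before scoring, each prey's control counts are collapsed to the two largest
values (`collapse_controls()`, `k = 2`), the standard conservative treatment
of pooled negative controls. The Bayesian FDR at rank $k$ is the running
mean of $(1 - \text{score})$ over the $k$ top-scoring preys, with tied
scores sharing the worst value of their block. Selection defaults to
BFDR $\le 0.02$ *or* score $\ge 0.80$; whether the two cuts are applied as a
disjunction or conjunction is a configuration switch (`rule`), since on
well-behaved screens they nearly coincide.

**Why the moderated control mean.** With only two retained control values, a
background prey whose controls are both zero by chance (probability
$e^{-n_c \lambda_{false}}$, a few percent at realistic rates) would get
$\lambda_{false} = c_0$ and a spuriously confident score; the resulting BFDR
understates the realized false-discovery proportion by roughly a factor of
two. One pseudo-observation at the experiment-wide control mean removes this
failure mode while leaving preys with informative controls essentially
untouched ($m = 0$ restores the unmoderated estimate). Measured on
synthetic screens (200 true preys at $\lambda_{true} = 20$, 800 background
preys at $\lambda_{false} = 0.5$, 20 replicates), selection at BFDR
$\le 0.02$ attains an empirical FDR of about 0.04 with sensitivity 1.0.
This scorer is deliberately simple — no protein-length normalization, no
informative priors — and is not intended to reproduce any specific published
interactor list numerically, only the threshold semantics.

## Peak-set algebra and TSS-proximity annotation

Peaks carry a normalized tag count and are filtered at a configurable
threshold (convention: $\ge 15$ tags, or $\ge 10$ for weaker antibodies).
Internally all coordinates are 0-based half-open; the HOMER reader shifts
its 1-based inclusive starts on input, so every downstream operation works
in one convention tested at the parser boundary.

Merging takes the connected components of the $\ge$ 1-bp-overlap graph
(transitive closure, so chains of pairwise-overlapping peaks merge into one
unit), the observable behavior of HOMER's `mergePeaks` on chains. A merged
peak spans the union of its members and records the contributing TF set;
`combination_counts()` tallies those sets, and the tally always sums to the
number of merged peaks. The engine is `GenomicRanges::reduce()` with
`min.gapwidth = 0` (book-ended intervals share no base and never merge);
the test suite checks it against a naive all-pairs implementation on
hundreds of random instances.

A peak is TSS-proximal to a gene when the distance between the peak
interval and the TSS is at most the window (2.5 kb by default), symmetric
upstream/downstream. Distance is measured to the half-open end coordinate
(a peak `[8000, 9000)` is 1000 bp from a TSS at 10000) and is 0 when the
TSS lies inside the peak. Each proximal peak is assigned to its single
closest TSS, ties broken by the lexicographically smaller gene id for
determinism; an `all_in_window` switch assigns to every gene in the window
instead, since published "closest gene" annotations are ambiguous on this
point.

## Chromatin loops and loop-mediated gene assignment

Loops are anchor pairs at a fixed bin size (5 kb default) with a
significance value; significance estimation itself is upstream of this
package, which consumes already-significant interactions. Replicate loop
sets are merged at one-bin tolerance: two loops match when both
anchor1–anchor1 and anchor2–anchor2 start offsets are $\le$ one bin, the
match relation is closed transitively, and a merged loop spans the union of
its members' anchors. Intra-chromosomal loops closer than two bins are kept
but flagged with a warning, to tolerate dialects. Anchor-pair TF patterns
are counted unordered by default (a loop has no intrinsic direction; the
non-empty subset is listed first in the canonical pattern), with an
`ordered` switch.

An anchor is TSS-proximal when any TSS lies within the window of the anchor
interval; it then lists *all* such genes (an anchor bin can cover several
promoters, and nothing in the assignment logic privileges one). A distal
peak — one farther than the window from every TSS — is assigned to every
gene of the TSS-proximal partner anchors of the loops it touches; distal
peaks touching no loop, or only loops whose partners are all distal, are
discarded. A gene's bound-TF set is then the union over proximal and loop
evidence, "independent of position", and genes are partitioned by their
exact bound set. When gene *categories* are instead defined over several
peak classes, genes hitting more than one category are excluded and
tallied (`unique_category_genes()`).

## Differential expression of bound gene sets

The expression stage tests whether genes bound by a factor respond to that
factor's mutation status. Contrasts name required lesion statuses per group
(e.g. PAX5-mutated vs PAX5-wildtype, or double-mutant vs single-mutant);
samples with unknown status for any referenced lesion are excluded first.
Genes need $\ge 10$ counts in $\ge 2$ of the contrast's samples, and
testing is restricted to the bound gene set *before* any test is run, so
the BH adjustment runs over exactly the tested subset.

The NB machinery is deliberately transparent rather than clever:
median-of-ratios size factors; per-gene method-of-moments dispersion
$\alpha = (\mathrm{var} - \mu)/\mu^2$ pooled within groups with a floor of
$10^{-4}$; a Wald test on the group coefficient of a two-group NB
log-linear model with the size factors as offsets. There is no dispersion
shrinkage toward a fitted trend, no fold-change shrinkage and no
independent filtering — the scientific content here is the bound-gene
restriction and the contrast design, not the NB estimator, and parameter
recovery on synthetic truth (not numerical identity with any particular
DE package) is the acceptance standard. On synthetic data the null
type-I error at nominal 0.05 is about 0.06, and planted 4-fold effects at
10 vs 10 samples are recovered with sensitivity $\ge 0.95$ and FDP near 0;
an independent cross-check in the test suite confirms fold-change agreement
($r > 0.98$) with DESeq2 on a shared instance. Calls use inclusive
boundaries: adjusted $p \le$ FDR and $|\log_2 FC| \ge \log_2(\text{fold})$.

Group-level comparison works on per-sample means of
$\log_2(\mathrm{RPKM} + 1)$ over a differential gene list
(RPKM = count / (exonic kb × library-size millions); the pseudo-value 1 is
a package choice, configurable). Category differences use the two-sided
Mann-Whitney U test — exact when both groups have $n < 20$ and no ties, the
tie-corrected normal approximation otherwise. Responsiveness comparisons
(e.g. bound-and-differential vs bound-only vs unbound genes) use per-pair
two-sample Kolmogorov-Smirnov statistics over category ECDFs.

## Co-mutation statistics

The mutation catalogue is a generic (tumor, gene, type, histology) table;
(tumor, gene) pairs are de-duplicated for all presence/absence analyses,
since multiple lesions of one gene in one tumor still mean "mutated". The
module reports: the share of all catalogued mutated genes that are PXIs and
the share of the PXI list found mutated; the presence matrix of co-mutated
genes across tumors carrying the focal mutation plus at least one other
(tumors with only the focal mutation drop out of the matrix but are counted
in `n_focal_tumors`); and per-histology PXI-mutation fractions. Per-gene
tallies can be read off the matrix either as mutated-sample counts or, from
the raw catalogue, as mutation counts — both views are available because
presence heatmaps and frequency barplots answer different questions.

## The synthetic-data module

The generators produce inputs with exactly the statistical structure the
analysis assumes, so every stage is testable against known truth without
external data. Design choices:

* **Layout.** Genes sit on a per-chromosome grid with spacing $\ge 12$
  bins and TSSs jittered within one bin. Each gene gets one proximal
  regulatory element (inside the TSS window) and `n_distal_per_gene` distal
  elements in bins 3–6 bins from the TSS bin. This guarantees elements
  never overlap, distal bins are $>$ window from every TSS, and anchor
  bins never capture a neighboring gene's promoter — so with
  `loop_rate = 1` and noise-free peaks the pipeline must recover the truth
  *exactly*, and any mismatch is a defect, not ambiguity.
* **Co-binding.** Each element draws its bound-TF subset from a
  configurable distribution over subsets (probabilities summing to
  $\le 1$; the remainder leaves the element unbound). The default places
  substantial mass on the all-four-factor class, reflecting the strong
  co-binding expected of a functional network.
* **Truth semantics.** A gene's true bound set is the union of its
  proximal element's TFs and its *looped* distal elements' TFs. TFs on
  unlooped distal elements are excluded from the gene truth deliberately:
  they are unrecoverable by loop-mediated annotation by construction, and
  the pipeline's discard rule is itself part of what is being tested.
* **BioID.** True preys draw Poisson($\lambda_{true}$) counts in bait runs
  and Poisson($\lambda_{false}$) in controls; background preys draw
  Poisson($\lambda_{false}$) everywhere. The default replicate structure is
  3 biological × 2 technical bait runs and 6 control runs, mirroring the
  same 3 × 2 design on the control side. Defaults
  $\lambda_{true} = 20$, $\lambda_{false} = 0.5$, 200 true / 800 background
  preys describe a clean, strongly separated screen.
* **Expression.** NB counts with log-normal gene means, dispersion 0.1,
  per-sample depth factors in [0.7, 1.3]; 10 samples per mutation class; a
  fraction (0.3) of the genes truly bound by the lesion factor carry a
  ±2 log2-fold effect in the mutated class. Only bound genes are eligible
  for effects, matching the restriction the DE stage relies on. Dispersion
  0 degrades gracefully to Poisson.
* **Mutations.** Tumors draw a histology label and a focal-gene mutation;
  PXI genes mutate with odds multiplied by `exp(comut_log_or)` in focally
  mutated tumors and `exp(lymphoid_log_or)` in lymphoid tumors. Log-OR 0
  switches an enrichment off exactly.
* **Determinism.** Every generator is a pure function of the seed via
  fixed per-generator substreams, so adding one generator never perturbs
  the fixtures of another.

What the generators do *not* emulate — and hence what passing tests do not
show about real data: read-level noise, peak-calling artifacts, copy-number
or GC bias in counts, loop-significance miscalls, correlated mutations
beyond the single focal/PXI enrichment, or batch structure in expression.
The end-to-end recovery checks certify the algebra and the statistics, not
robustness to upstream measurement error.

## Numerical choices and degenerate inputs

* Interval-to-point distance is measured to the half-open boundary, 0
  inside; all window comparisons are boundary-inclusive.
* Ties: proximal assignment breaks ties to the smaller gene id; tied
  scores share the worst BFDR of their block; the unordered anchor pattern
  puts the non-empty (then lexicographically smaller) subset first.
* Empty inputs return empty, correctly-typed results; invalid
  configurations raise classed errors (`proxinet_config_error`,
  `proxinet_contract_error`, `proxinet_parse_error`) with the offending
  field or line.
* Genes with zero total count inside a tested subset are dropped with a
  message; NB fits that fail return NA statistics rather than aborting the
  table.
* Problem sizes in the tests and the acceptance script (120–150 genes,
  1000 preys, 10 vs 10 samples, 20 Monte-Carlo replicates) were chosen as
  the smallest instances at which the binomial/Poisson error bands in the
  checks are meaningfully tight.

## The pipeline runner

`run_pipeline()` executes the stages in dependency order from a single
validated configuration (R list, YAML or JSON), writes every stage output
as TSV/BED/BEDPE into a flat run directory, and records a machine-readable
manifest with parameters, input checksums, per-stage record counts in/out
(so every "n surviving" along the way is auditable) and output checksums;
a rerun with the same configuration is bit-identical. A stage failure
leaves partial outputs in place, writes a `failed/<stage>` marker and
aborts with the stage name. The exported stage functions and the runner
are the package's interface; there is no shell wrapper, because users of
this kind of analysis drive it from R scripts.

## Known limitations

The scorer assumes Poisson spectral counts (no overdispersion) and a
uniform prior; the NB test is unshrunk and can be anticonservative at very
small $n$ or very low counts; loop-mediated assignment inherits the bin
resolution (a promoter and an enhancer in one bin are indistinguishable);
and the co-mutation module deliberately stops at descriptive statistics —
no mutual-exclusivity testing.
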
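#' De-duplicate a mutation catalogue to gene presence per tumor
#'
#' Presence/absence analyses collapse multiple mutations of one gene in
#' one tumor to a single record; re-running on its own output changes
#' nothing.
#'
#' @param catalogue data.frame with `tumor_id`, `gene` and optionally
#'   `mutation_type`, `histology`.
#' @return de-duplicated catalogue (first record per tumor/gene pair).
#' @export
dedup_catalogue <- function(catalogue) {
  stopifnot_cols(catalogue, c("tumor_id", "gene"), "mutation catalogue")
  out <- catalogue[!duplicated(catalogue[, c("tumor_id", "gene")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of mutated genes that are PXIs, and of PXIs found mutated
#'
#' Two complementary views of PXI involvement in a tumor catalogue: the
#' share of all catalogued mutated genes that appear on the PXI list, and
#' the share of the PXI list observed mutated at all.
#'
#' @param catalogue mutation catalogue.
#' @param pxi_list character vector of PXI gene symbols.
#' @return list: `frac_mutated_genes_pxi`, `frac_pxis_mutated`, with
#'   numerators and denominators (`n_mutated_genes`, `n_pxis`,
#'   `n_mutated_pxis`).
#' @export
pxi_mutation_fractions <- function(catalogue, pxi_list) {
  catalogue <- dedup_catalogue(catalogue)
  pxi_list <- unique(as.character(pxi_list))
  mutated <- unique(catalogue$gene)
  n_mut_pxi <- sum(mutated %in% pxi_list)
  list(
    frac_mutated_genes_pxi = if (length(mutated)) n_mut_pxi / length(mutated) else 0,
    frac_pxis_mutated = if (length(pxi_list)) n_mut_pxi / length(pxi_list) else 0,
    n_mutated_genes = length(mutated),
    n_pxis = length(pxi_list),
    n_mutated_pxis = n_mut_pxi
  )
}

#' Co-mutation presence matrix for tumors carrying a focal mutation
#'
#' Rows are the tumors mutated in `focal_gene` that carry at least one
#' additional mutated gene; columns are those co-mutated genes; entries
#' are presence (TRUE/FALSE). Genes on the PXI list are flagged.
#'
#' @param catalogue mutation catalogue.
#' @param focal_gene the focal gene (must appear in the catalogue).
#' @param pxi_list PXI gene symbols used for the column flag.
#' @return list with `matrix` (tumor x gene logical), `pxi_flag` (named
#'   logical per column) and `n_focal_tumors` (all tumors with the focal
#'   mutation, including those without co-mutations).
#' @export
comutation_matrix <- function(catalogue, focal_gene, pxi_list = character(0)) {
  catalogue <- dedup_catalogue(catalogue)
  if (!focal_gene %in% catalogue$gene) {
    contract_error(sprintf("focal gene '%s' absent from the catalogue", focal_gene))
  }
  focal_tumors <- unique(catalogue$tumor_id[catalogue$gene == focal_gene])
  co <- catalogue[catalogue$tumor_id %in% focal_tumors & catalogue$gene != focal_gene, , drop = FALSE]
  tumors <- sort(unique(co$tumor_id))
  genes <- sort(unique(co$gene))
  m <- matrix(FALSE, length(tumors), length(genes), dimnames = list(tumors, genes))
  if (nrow(co)) m[cbind(co$tumor_id, co$gene)] <- TRUE
  list(matrix = m,
       pxi_flag = setNames(genes %in% pxi_list, genes),
       n_focal_tumors = length(focal_tumors))
}

#' PXI-mutated tumor fraction per histology
#'
#' For each histology label: the fraction of its tumors carrying at least
#' one mutated PXI gene, with counts. Labels with zero tumors do not
#' appear.
#'
#' @param catalogue mutation catalogue (needs a `histology` column).
#' @param pxi_list PXI gene symbols.
#' @return data.frame: `histology`, `n_tumors`, `n_pxi_mutated`, `fraction`.
#' @export
histology_breakdown <- function(catalogue, pxi_list) {
  stopifnot_cols(catalogue, c("tumor_id", "gene", "histology"), "mutation catalogue")
  catalogue <- dedup_catalogue(catalogue)
  per_tumor <- split(catalogue$gene, catalogue$tumor_id)
  hist_of <- vapply(split(catalogue$histology, catalogue$tumor_id), `[`, "", 1)
  has_pxi <- vapply(per_tumor, function(g) any(g %in% pxi_list), TRUE)
  tab <- table(hist_of)
  hit <- tapply(has_pxi, hist_of, sum)
  out <- data.frame(
    histology = names(tab),
    n_tumors = as.integer(tab),
    n_pxi_mutated = as.integer(hit[names(tab)]),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$n_pxi_mutated / out$n_tumors
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
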
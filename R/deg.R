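# DEG filtering and the joins producing the headline sets: DEGs with
# promoter rSNPs, important rSNPs per tissue, DEGs harboring important
# rSNPs, and Venn-region tallies across tissues.

#' Filter a DEG table into up- and down-regulated sets
#'
#' Strict inequalities on both axes: up-regulated means `log2fc > lfc` and
#' `padj < alpha`; down-regulated means `log2fc < -lfc` and `padj < alpha`.
#' Rows at the boundary (`log2fc == lfc`, `padj == alpha`) and rows with
#' `padj = NA` are excluded.
#'
#' @param deg DEG data.frame (see [read_deg_table()]).
#' @param lfc Absolute log2 fold-change threshold (default 2).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @return A list with character vectors `up` and `down`.
#' @export
filter_degs <- function(deg, lfc = 2, alpha = 0.05) {
  sig <- !is.na(deg$padj) & deg$padj < alpha
  list(up = deg$gene[sig & deg$log2fc > lfc],
       down = deg$gene[sig & deg$log2fc < -lfc])
}

#' DEGs carrying promoter rSNPs, per tissue
#'
#' For each tissue's DEG set, returns the genes with at least one rSNP in
#' their promoter together with the rSNP count. Both the SNP-level count
#' (distinct rSNPs) and row-level pairs are derivable from the output.
#'
#' @param deg_sets Named list (tissue -> character vector of DEG ids, up
#'   and down combined or as supplied).
#' @param rsnp_gene_map Data.frame with columns `snp_id`, `gene_id` (rSNP
#'   promoter assignments, see [annotate_rsnp_positions()]).
#' @return Named list of data.frames with columns `gene_id`, `n_rsnps`.
#' @export
degs_with_rsnps <- function(deg_sets, rsnp_gene_map) {
  lapply(deg_sets, function(genes) {
    sub <- rsnp_gene_map[rsnp_gene_map$gene_id %in% genes, , drop = FALSE]
    if (nrow(sub) == 0L)
      return(data.frame(gene_id = character(), n_rsnps = integer(),
                        stringsAsFactors = FALSE))
    counts <- tapply(sub$snp_id, sub$gene_id,
                     function(x) length(unique(x)))
    out <- data.frame(gene_id = names(counts),
                      n_rsnps = as.integer(counts),
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene_id), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Important rSNPs restricted to each tissue's DEG promoters
#'
#' @param important Character vector of important rSNP ids (consensus
#'   output).
#' @param rsnp_gene_map Data.frame with columns `snp_id`, `gene_id`.
#' @param deg_sets Named list (tissue -> DEG gene ids).
#' @return Named list of data.frames with columns `snp_id`, `gene_id`
#'   (SNP x gene level); the SNP-level tally is
#'   `length(unique(out$snp_id))`.
#' @export
important_rsnps_per_tissue <- function(important, rsnp_gene_map,
                                       deg_sets) {
  lapply(deg_sets, function(genes) {
    sub <- rsnp_gene_map[rsnp_gene_map$snp_id %in% important &
                           rsnp_gene_map$gene_id %in% genes,
                         c("snp_id", "gene_id"), drop = FALSE]
    sub <- sub[order(sub$snp_id, sub$gene_id), , drop = FALSE]
    rownames(sub) <- NULL
    sub
  })
}

#' Venn-region counts across sets
#'
#' Counts elements in every one of the `2^k - 1` intersection regions of
#' `k` named sets; region labels join set names with `&`. Counts sum to
#' the size of the union.
#'
#' @param sets Named list of two or more character vectors.
#' @return A data.frame with columns `region` and `count`.
#' @export
venn_counts <- function(sets) {
  stopifnot(length(sets) >= 2L, !is.null(names(sets)))
  k <- length(sets)
  universe <- unique(unlist(sets, use.names = FALSE))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  colnames(combos) <- names(sets)
  region <- apply(combos, 1L, function(inc)
    paste(names(sets)[as.logical(inc)], collapse = "&"))
  count <- apply(combos, 1L, function(inc) {
    inc <- as.logical(inc)
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(m) all(m == inc)))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE)
}
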
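#' Nonsynonymous SNP density per codon for one GO term
#'
#' The term's statistic is the total density of nonsynonymous SNPs per
#' codon over all gene models annotated with the term:
#' sum(ns_snp_count) / sum(codon_count).
#'
#' @param term GO term identifier.
#' @param loads data frame with columns `gene_id`, `ns_snp_count`,
#'   `codon_count`.
#' @param annotations data frame with columns `gene_id`, `term_id`.
#' @return scalar density.
#' @export
term_density <- function(term, loads, annotations) {
  genes <- unique(annotations$gene_id[annotations$term_id == term])
  if (length(genes) == 0L) stop(sprintf("term '%s' annotates no genes", term))
  sub <- loads[loads$gene_id %in% genes, , drop = FALSE]
  if (nrow(sub) == 0L) stop(sprintf("term '%s' annotates no genes with load data", term))
  sum(sub$ns_snp_count) / sum(sub$codon_count)
}

#' Permutation test for GO-term nonsynonymous enrichment
#'
#' For every term, the observed per-codon nonsynonymous density is compared
#' with densities obtained by randomly shuffling the per-gene
#' (ns_snp_count, codon_count) pairs across gene identities while the
#' gene-to-term annotation stays fixed. The tail is "greater than or equal
#' to" and the p-value uses the add-one estimator (n_geq + 1) /
#' (n_permutations + 1), so it can never be exactly zero at finite
#' permutations. Shuffling the two quantities as a pair preserves the
#' length-count association; independent shuffling of the two columns is
#' available for sensitivity analysis via `paired = FALSE`.
#'
#' @param loads data frame with `gene_id`, `ns_snp_count`, `codon_count`
#'   (>= 2 genes).
#' @param annotations data frame with `gene_id`, `term_id`.
#' @param n_permutations number of permutations (default 1000).
#' @param seed integer seed; results are seed-reproducible.
#' @param paired shuffle (ns, codons) as paired units (default) or each
#'   column independently.
#' @return data frame with one row per term: `term_id`, `n_genes`,
#'   `observed_density`, `n_permutations`, `n_geq`, `p_value`, `q_value`
#'   (Benjamini-Hochberg), sorted by `term_id`.
#' @export
go_permutation_test <- function(loads, annotations, n_permutations = 1000L,
                                seed = 1L, paired = TRUE) {
  stopifnot(all(c("gene_id", "ns_snp_count", "codon_count") %in% names(loads)),
            all(c("gene_id", "term_id") %in% names(annotations)),
            n_permutations >= 1L)
  if (nrow(loads) < 2L)
    stop("permutation over a single gene is degenerate; need >= 2 genes")
  if (any(loads$codon_count <= 0)) stop("codon_count must be positive")
  loads <- loads[order(loads$gene_id), , drop = FALSE]
  ann <- annotations[annotations$gene_id %in% loads$gene_id, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  terms <- sort(unique(ann$term_id))
  n_genes <- nrow(loads)
  M <- Matrix::sparseMatrix(
    i = match(ann$term_id, terms),
    j = match(ann$gene_id, loads$gene_id),
    x = 1, dims = c(length(terms), n_genes))
  ns <- loads$ns_snp_count
  co <- loads$codon_count
  obs_ns <- as.numeric(M %*% ns)
  obs_co <- as.numeric(M %*% co)
  observed <- obs_ns / obs_co
  set.seed(seed)
  NS <- matrix(0, n_genes, n_permutations)
  CO <- matrix(0, n_genes, n_permutations)
  for (k in seq_len(n_permutations)) {
    p <- sample.int(n_genes)
    NS[, k] <- ns[p]
    if (paired) CO[, k] <- co[p] else CO[, k] <- co[sample.int(n_genes)]
  }
  perm_dens <- as.matrix(M %*% NS) / as.matrix(M %*% CO)
  ## counts are integers, so equal sums compare exactly
  n_geq <- Matrix::rowSums(perm_dens >= observed)
  p_value <- (n_geq + 1) / (n_permutations + 1)
  data.frame(term_id = terms,
             n_genes = as.integer(Matrix::rowSums(M)),
             observed_density = observed,
             n_permutations = as.integer(n_permutations),
             n_geq = as.integer(n_geq),
             p_value = p_value,
             q_value = p.adjust(p_value, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Terms significant at a raw p-value threshold
#'
#' No multiple-testing correction is applied to the selection (the
#' Benjamini-Hochberg `q_value` column travels alongside for reference).
#'
#' @param results output of [go_permutation_test()].
#' @param alpha raw p-value threshold (default 0.01).
#' @return the significant rows, sorted by ascending p-value.
#' @export
significant_terms <- function(results, alpha = 0.01) {
  stopifnot(nrow(results) > 0L)
  out <- results[results$p_value < alpha, , drop = FALSE]
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
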
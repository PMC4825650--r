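## Nei-Gojobori (1986) counting machinery.
##
## Expected synonymous sites per codon: at each position, the fraction of the
## three possible changes that preserve the amino acid (changes creating a
## stop count as nonsynonymous opportunities). Sites for a pairwise
## comparison are averaged over the two sequences.

.codon_site_cache <- new.env(parent = emptyenv())

.codon_sites <- function(codon) {
  hit <- .codon_site_cache[[codon]]
  if (!is.null(hit)) return(hit)
  gc_tab <- Biostrings::GENETIC_CODE
  aa <- gc_tab[[codon]]
  chars <- strsplit(codon, "")[[1]]
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(.BASES, chars[p])) {
      mut <- chars
      mut[p] <- b
      if (gc_tab[[paste(mut, collapse = "")]] == aa) syn <- syn + 1 / 3
    }
  }
  res <- c(syn = syn, nonsyn = 3 - syn)
  assign(codon, res, envir = .codon_site_cache)
  res
}

.perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in .perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## Average synonymous/nonsynonymous step counts over all minimal mutational
## pathways between two codons; pathways through an intermediate stop codon
## are discarded unless every pathway passes through one.
.pathway_counts <- function(ref_codon, alt_codon) {
  gc_tab <- Biostrings::GENETIC_CODE
  rc <- strsplit(ref_codon, "")[[1]]
  ac <- strsplit(alt_codon, "")[[1]]
  d <- which(rc != ac)
  if (length(d) == 0L) return(c(syn = 0, nonsyn = 0))
  paths <- .perms(d)
  res <- lapply(paths, function(ord) {
    cur <- rc; syn <- 0L; nonsyn <- 0L; valid <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- ac[ord[k]]
      if (gc_tab[[paste(cur, collapse = "")]] ==
          gc_tab[[paste(nxt, collapse = "")]]) syn <- syn + 1L
      else nonsyn <- nonsyn + 1L
      if (k < length(ord) && gc_tab[[paste(nxt, collapse = "")]] == "*")
        valid <- FALSE
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, valid = valid)
  })
  valid <- vapply(res, function(x) x$valid, logical(1))
  use <- if (any(valid)) res[valid] else res
  c(syn = mean(vapply(use, function(x) x$syn, numeric(1))),
    nonsyn = mean(vapply(use, function(x) x$nonsyn, numeric(1))))
}

#' Per-gene dN and dS against the reference by Nei-Gojobori counting
#'
#' The gene's SNPs are substituted into the reference CDS (codon-aligned by
#' construction, no gaps) and synonymous/nonsynonymous substitutions are
#' counted per changed codon, averaging over all minimal mutational pathways
#' for multi-hit codons. Expected synonymous and nonsynonymous site counts
#' are averaged over the reference and mutant sequences. The terminal stop
#' codon is excluded from all counts. A variant turning an internal codon
#' into a stop flags the record and that codon is dropped from the counts.
#' dN and dS are proportions of substitutions per site; an optional
#' Jukes-Cantor correction is available (default off: within-species
#' divergence here is far below saturation).
#'
#' @param gene_id gene identifier present in `models$genes`.
#' @param models gene models (see [classify_effects()]).
#' @param reference named [Biostrings::DNAStringSet].
#' @param variants call table for this gene; every variant must fall inside
#'   the gene's CDS.
#' @param jc_correction apply the Jukes-Cantor multiple-hit correction.
#' @return one-row data frame: `gene_id`, `n_sites`, `s_sites`, `n_subs`,
#'   `s_subs`, `dN`, `dS`, `premature_stop`. `dN`/`dS` are `NA` when the
#'   corresponding site count is zero.
#' @export
gene_dnds <- function(gene_id, models, reference, variants,
                      jc_correction = FALSE) {
  gm <- list(genes = models$genes[models$genes$gene_id == gene_id, , drop = FALSE],
             exons = models$exons[models$exons$gene_id == gene_id, , drop = FALSE])
  if (nrow(gm$genes) == 0L) stop(sprintf("unknown gene model '%s'", gene_id))
  g <- .gene_cds(gm, reference)[[1]]
  cds_ref <- g$cds
  n_codons <- length(cds_ref) %/% 3L
  mut <- cds_ref
  if (!is.null(variants) && nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      pos <- variants$position[i]
      e <- g$exons[g$exons$start <= pos & g$exons$end >= pos, , drop = FALSE]
      if (nrow(e) == 0L)
        stop(sprintf("variant at %s:%d lies outside the CDS of %s",
                     variants$chromosome[i], pos, gene_id))
      e <- e[1L, ]
      t_idx <- if (g$strand == "+") e$t_offset + pos - e$start + 1L
               else e$t_offset + e$end - pos + 1L
      alt <- if (g$strand == "+") variants$alt_allele[i]
             else unname(.COMPLEMENT[variants$alt_allele[i]])
      mut[t_idx] <- alt
    }
  }
  gc_tab <- Biostrings::GENETIC_CODE
  ## codons 1 .. n_codons-1 (terminal stop dropped)
  usable <- seq_len(n_codons - 1L)
  premature <- FALSE
  excluded <- logical(length(usable))
  codon_str <- function(x, k) paste(x[(3L * (k - 1L) + 1L):(3L * k)], collapse = "")
  n_subs <- s_subs <- 0
  n_sites <- s_sites <- 0
  for (k in usable) {
    rc <- codon_str(cds_ref, k)
    mc <- codon_str(mut, k)
    if (mc != rc && gc_tab[[mc]] == "*") {
      premature <- TRUE
      excluded[k] <- TRUE
      next
    }
    sr <- .codon_sites(rc)
    sm <- .codon_sites(mc)
    s_sites <- s_sites + (sr[["syn"]] + sm[["syn"]]) / 2
    n_sites <- n_sites + (sr[["nonsyn"]] + sm[["nonsyn"]]) / 2
    if (mc != rc) {
      pc <- .pathway_counts(rc, mc)
      s_subs <- s_subs + pc[["syn"]]
      n_subs <- n_subs + pc[["nonsyn"]]
    }
  }
  pn <- if (n_sites > 0) n_subs / n_sites else NA_real_
  ps <- if (s_sites > 0) s_subs / s_sites else NA_real_
  if (jc_correction) {
    jc <- function(p) if (is.na(p) || p >= 0.75) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
    pn <- jc(pn); ps <- jc(ps)
  }
  data.frame(gene_id = gene_id, n_sites = n_sites, s_sites = s_sites,
             n_subs = n_subs, s_subs = s_subs, dN = pn, dS = ps,
             premature_stop = premature, stringsAsFactors = FALSE)
}

#' dN/dS records for every gene from a classified call table
#'
#' Convenience wrapper: groups coding calls by gene (one variant per distinct
#' site-allele pair) and runs [gene_dnds()] on each gene model, including
#' variant-free genes (dN = dS = 0).
#'
#' @param classified output of [classify_effects()] on a filtered,
#'   hemi-cleaned call set.
#' @inheritParams gene_dnds
#' @return data frame of per-gene records (one row per gene model).
#' @export
dnds_table <- function(classified, models, reference, jc_correction = FALSE) {
  coding <- classified[!is.na(classified$gene_id), , drop = FALSE]
  coding <- coding[!duplicated(paste(coding$gene_id, coding$chromosome,
                                     coding$position, coding$alt_allele)), ,
                   drop = FALSE]
  by_gene <- split(coding, coding$gene_id)
  rows <- lapply(models$genes$gene_id, function(id)
    gene_dnds(id, models, reference, by_gene[[id]], jc_correction))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genome-wide aggregate dN/dS as a ratio of means
#'
#' The genome-wide statistic is mean(dN) / mean(dS) across genes with
#' defined rates. A ratio of means is used (rather than a mean of per-gene
#' ratios) because at low within-species divergence most genes have dS = 0
#' and no defined per-gene ratio.
#'
#' @param records data frame of per-gene records (see [gene_dnds()]).
#' @return scalar aggregate ratio.
#' @export
aggregate_dnds <- function(records) {
  ok <- !is.na(records$dN) & !is.na(records$dS)
  if (!any(ok)) stop("no genes with defined dN and dS")
  mds <- mean(records$dS[ok])
  if (mds == 0) stop("mean dS is zero: aggregate dN/dS undefined")
  mean(records$dN[ok]) / mds
}

#' Paired bootstrap confidence interval for the aggregate dN/dS
#'
#' Resamples gene-level (dN, dS) pairs jointly with replacement, recomputes
#' the ratio-of-means aggregate for each bootstrap sample, and reports the
#' percentile interval. Replicates whose resampled mean dS is zero are
#' redrawn and counted.
#'
#' @param records per-gene records with `dN`, `dS` columns (>= 2 rows with
#'   defined rates).
#' @param n_boot number of bootstrap samples (default 10000).
#' @param level confidence level (default 0.95).
#' @param seed integer seed; the same seed reproduces the interval exactly.
#' @return list of class `"bootstrap_ci"`: `point`, `lower`, `upper`,
#'   `n_boot`, `level`, `seed`, `n_redrawn`.
#' @export
bootstrap_dnds_ci <- function(records, n_boot = 10000L, level = 0.95,
                              seed = 1L) {
  ok <- !is.na(records$dN) & !is.na(records$dS)
  r <- records[ok, , drop = FALSE]
  if (nrow(r) < 2L) stop("need at least 2 genes with defined rates")
  stopifnot(level > 0, level < 1, n_boot >= 1L)
  set.seed(seed)
  n <- nrow(r)
  point <- aggregate_dnds(r)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  mdn <- colMeans(matrix(r$dN[idx], nrow = n))
  mds <- colMeans(matrix(r$dS[idx], nrow = n))
  n_redrawn <- 0L
  bad <- which(mds == 0)
  while (length(bad)) {
    n_redrawn <- n_redrawn + length(bad)
    idx2 <- matrix(sample.int(n, n * length(bad), replace = TRUE), nrow = n)
    mdn[bad] <- colMeans(matrix(r$dN[idx2], nrow = n))
    mds[bad] <- colMeans(matrix(r$dS[idx2], nrow = n))
    bad <- bad[mds[bad] == 0]
  }
  ratios <- mdn / mds
  alpha <- 1 - level
  qs <- unname(quantile(ratios, c(alpha / 2, 1 - alpha / 2)))
  out <- list(point = point, lower = qs[1L], upper = qs[2L],
              n_boot = as.integer(n_boot), level = level,
              seed = as.integer(seed), n_redrawn = n_redrawn)
  class(out) <- "bootstrap_ci"
  out
}

#' @exportS3Method base::print
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("aggregate dN/dS = %.4f, %d%% paired-bootstrap CI [%.4f, %.4f] (%d samples)\n",
              x$point, round(100 * x$level), x$lower, x$upper, x$n_boot))
  invisible(x)
}
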
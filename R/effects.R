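.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## Per-gene CDS structures: transcript sequence (character vector) and the
## exon table with transcript-coordinate offsets, in transcript rank order.
.gene_cds <- function(models, reference) {
  genes <- models$genes
  exons <- models$exons
  out <- vector("list", nrow(genes))
  names(out) <- genes$gene_id
  for (i in seq_len(nrow(genes))) {
    id <- genes$gene_id[i]
    gex <- exons[exons$gene_id == id, , drop = FALSE]
    gex <- gex[order(gex$rank), , drop = FALSE]
    strand <- genes$strand[i]
    chrom <- genes$chromosome[i]
    pieces <- lapply(seq_len(nrow(gex)), function(e) {
      s <- strsplit(as.character(Biostrings::subseq(
        reference[[chrom]], gex$start[e], gex$end[e])), "")[[1]]
      if (strand == "-") rev(unname(.COMPLEMENT[s])) else s
    })
    widths <- gex$end - gex$start + 1L
    gex$t_offset <- cumsum(c(0L, head(widths, -1L)))
    cds <- unlist(pieces)
    if (length(cds) %% 3L != 0L)
      stop(sprintf("gene model %s: CDS length %d not divisible by 3",
                   id, length(cds)))
    out[[i]] <- list(gene_id = id, chromosome = chrom, strand = strand,
                     exons = gex, cds = cds)
  }
  out
}

#' Classify SNP calls as noncoding, synonymous, or nonsynonymous
#'
#' A call is noncoding if it does not fall in the coding region of any gene
#' model. Coding calls are placed into their codon using the gene's CDS
#' structure (minus-strand calls are complemented before codon substitution)
#' and translated with the standard genetic code: amino-acid identity means
#' synonymous, anything else nonsynonymous. A call inside the CDS of more
#' than one gene model is classified once per model (one output row per
#' call-model pair).
#'
#' @param calls data frame of calls (`chromosome`, `position`, `ref_allele`,
#'   `alt_allele`, ...).
#' @param models gene models: list with `genes` (gene_id, chromosome, strand,
#'   start, end, codon_count) and `exons` (gene_id, chromosome, strand,
#'   start, end, rank).
#' @param reference named [Biostrings::DNAStringSet] of chromosome sequences.
#' @return `calls` with added columns `gene_id`, `codon_index`, `ref_codon`,
#'   `alt_codon`, `ref_aa`, `alt_aa`, `effect`; noncoding calls carry
#'   `gene_id = NA` and `effect = "noncoding"`. One row per call-model pair.
#' @export
classify_effects <- function(calls, models, reference) {
  .validate_calls(calls, require_evidence = FALSE)
  cds_list <- .gene_cds(models, reference)
  gc_tab <- Biostrings::GENETIC_CODE

  ## map each call to the exons containing it
  ex <- models$exons
  n <- nrow(calls)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    chrom <- calls$chromosome[i]
    pos <- calls$position[i]
    ref_base <- as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
    if (ref_base != calls$ref_allele[i])
      stop(sprintf("reference mismatch at %s:%d: reference has %s, call has %s",
                   chrom, pos, ref_base, calls$ref_allele[i]))
    hit <- which(ex$chromosome == chrom & ex$start <= pos & ex$end >= pos)
    base <- calls[i, , drop = FALSE]
    if (length(hit) == 0L) {
      base$gene_id <- NA_character_
      base$codon_index <- NA_integer_
      base$ref_codon <- base$alt_codon <- NA_character_
      base$ref_aa <- base$alt_aa <- NA_character_
      base$effect <- "noncoding"
      rows[[i]] <- base
      next
    }
    per_gene <- lapply(unique(ex$gene_id[hit]), function(id) {
      g <- cds_list[[id]]
      e <- g$exons[g$exons$start <= pos & g$exons$end >= pos, , drop = FALSE][1L, ]
      t_idx <- if (g$strand == "+") e$t_offset + pos - e$start + 1L
               else e$t_offset + e$end - pos + 1L
      cds_ref <- g$cds[t_idx]
      call_ref <- if (g$strand == "+") calls$ref_allele[i]
                  else unname(.COMPLEMENT[calls$ref_allele[i]])
      if (cds_ref != call_ref)
        stop(sprintf("reference mismatch inside CDS of %s at %s:%d", id, chrom, pos))
      alt <- if (g$strand == "+") calls$alt_allele[i]
             else unname(.COMPLEMENT[calls$alt_allele[i]])
      ci <- (t_idx - 1L) %/% 3L + 1L
      cpos <- (t_idx - 1L) %% 3L + 1L
      ref_codon <- paste(g$cds[(3L * (ci - 1L) + 1L):(3L * ci)], collapse = "")
      alt_chars <- strsplit(ref_codon, "")[[1]]
      alt_chars[cpos] <- alt
      alt_codon <- paste(alt_chars, collapse = "")
      r <- base
      r$gene_id <- id
      r$codon_index <- ci
      r$ref_codon <- ref_codon
      r$alt_codon <- alt_codon
      r$ref_aa <- unname(gc_tab[[ref_codon]])
      r$alt_aa <- unname(gc_tab[[alt_codon]])
      r$effect <- if (r$ref_aa == r$alt_aa) "synonymous" else "nonsynonymous"
      r
    })
    rows[[i]] <- do.call(rbind, per_gene)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collapse per-model effect rows to one class per call
#'
#' For density accounting each SNP is counted once; a call that is
#' nonsynonymous in any overlapping model is counted as nonsynonymous,
#' then synonymous, else noncoding.
#'
#' @param classified output of [classify_effects()].
#' @return one row per distinct (chromosome, position, alt_allele) with an
#'   `effect` column.
#' @export
call_effect_classes <- function(classified) {
  key <- .call_key(classified)
  rank <- c(nonsynonymous = 1L, synonymous = 2L, noncoding = 3L)
  ord <- order(key, rank[classified$effect])
  first <- !duplicated(key[ord])
  out <- classified[ord, , drop = FALSE][first, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP density per chromosome and effect category
#'
#' SNP density is the number of SNPs within a given length of
#' callable sequence, reported as a percentage. Rows cover the categories
#' noncoding, synonymous, nonsynonymous, and total (their sum) for each
#' chromosome in the callable table; the `genome` column is the subgenome
#' letter (leading character of the chromosome name).
#'
#' @param classified one-row-per-call classified table
#'   (see [call_effect_classes()]).
#' @param callable data frame of callable intervals (`chromosome`, `start`,
#'   `end`, 1-based inclusive).
#' @return data frame with columns `chromosome`, `genome`, `category`,
#'   `snp_count`, `callable_length`, `density` (percent).
#' @export
compute_density <- function(classified, callable) {
  stopifnot(all(c("chromosome", "start", "end") %in% names(callable)))
  lens <- tapply(callable$end - callable$start + 1L, callable$chromosome, sum)
  chroms <- names(lens)
  extra <- setdiff(unique(classified$chromosome), chroms)
  if (length(extra))
    stop("calls on chromosome(s) with zero callable length: ",
         paste(extra, collapse = ", "))
  cats <- c("noncoding", "synonymous", "nonsynonymous")
  rows <- list()
  for (ch in chroms) {
    len <- as.integer(lens[[ch]])
    if (len <= 0L) stop(sprintf("zero callable length on %s", ch))
    sub <- classified[classified$chromosome == ch, , drop = FALSE]
    counts <- vapply(cats, function(k) sum(sub$effect == k), integer(1))
    counts <- c(counts, total = sum(counts))
    rows[[ch]] <- data.frame(chromosome = ch,
                             genome = substr(ch, 1L, 1L),
                             category = names(counts),
                             snp_count = as.integer(counts),
                             callable_length = len,
                             density = 100 * counts / len,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-genome density averages with standard deviations across chromosomes
#'
#' @param density_table output of [compute_density()].
#' @return data frame with columns `genome` (subgenome letter or "all"),
#'   `category`, `mean_density`, `sd_density`, `n_chromosomes`.
#' @export
density_summary <- function(density_table) {
  groups <- c(split(density_table, density_table$genome),
              list(all = density_table))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    agg <- do.call(rbind, lapply(split(d, d$category), function(x)
      data.frame(genome = g, category = x$category[1L],
                 mean_density = mean(x$density),
                 sd_density = sd(x$density),
                 n_chromosomes = nrow(x), stringsAsFactors = FALSE)))
    agg
  }))
  rownames(out) <- NULL
  out
}

#' Welch t-test comparing per-chromosome SNP densities of two subgenomes
#'
#' @param density_A,density_C numeric vectors of per-chromosome densities
#'   (at least two values each).
#' @return list with `statistic` (t), `p_value` (two-sided), `df`,
#'   `mean_A`, `mean_C`.
#' @export
compare_genome_densities <- function(density_A, density_C) {
  if (length(density_A) < 2L || length(density_C) < 2L)
    stop("need at least 2 per-chromosome density values per genome")
  if (sd(density_A) == 0 && sd(density_C) == 0 &&
      mean(density_A) == mean(density_C)) {
    return(list(statistic = 0, p_value = 1,
                df = length(density_A) + length(density_C) - 2,
                mean_A = mean(density_A), mean_C = mean(density_C)))
  }
  tt <- t.test(density_A, density_C, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_A = mean(density_A), mean_C = mean(density_C))
}

#' Chi-square test of equal divergence from the reference
#'
#' Tests whether the two parents' SNP counts against a shared reference are
#' consistent with equal divergence: the expectation is the mean of the two
#' counts and the statistic is the two-category goodness-of-fit chi-square
#' with one degree of freedom.
#'
#' @param count_parent1,count_parent2 observed SNP counts (>= 0, not both 0).
#' @return list with `expected`, `statistic`, `df`, `p_value`.
#' @examples
#' equal_divergence_test(355048, 789793)$expected  # 572420.5
#' @export
equal_divergence_test <- function(count_parent1, count_parent2) {
  if (count_parent1 < 0 || count_parent2 < 0)
    stop("counts must be non-negative")
  if (count_parent1 + count_parent2 == 0)
    stop("counts must not both be zero")
  expected <- (count_parent1 + count_parent2) / 2
  obs <- c(count_parent1, count_parent2)
  statistic <- sum((obs - expected)^2 / expected)
  list(expected = expected, statistic = statistic, df = 1L,
       p_value = pchisq(statistic, df = 1L, lower.tail = FALSE))
}
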
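#' Simulation configuration for a reference + two-parent genome trio
#'
#' Bundles and validates the knobs of the synthetic genome-trio generator.
#' Defaults emulate the desk-scale study design: two inbred parents resequenced
#' against a shared reference, per-parent divergence around 0.6%, reduced
#' divergence inside coding sequence, hemi-SNP artifacts from homeologous
#' mapping, about 82% of each chromosome callable at >= 5x coverage, and a
#' large retroelement-like insertion planted in one focal flowering gene.
#'
#' @param seed integer seed; the same seed reproduces the trio byte for byte.
#' @param n_chromosomes number of chromosomes; names alternate between the A
#'   and C subgenomes ("A01", "C01", ...).
#' @param chromosome_length length of each chromosome in bp.
#' @param n_genes total number of single-transcript gene models.
#' @param mean_cds_length mean CDS length in codons (including the stop).
#' @param mutation_rate_parent1,mutation_rate_parent2 per-site probability
#'   that a callable site differs from the reference in that parent only.
#' @param shared_mutation_rate per-site probability of a variant planted in
#'   both parents (same alternate allele), populating the shared list of the
#'   three-way comparison.
#' @param coding_rate_scale multiplier in \[0, 1\] applied to the mutation rate
#'   inside CDS.
#' @param ts_tv_ratio transition/transversion ratio used when drawing
#'   alternate alleles.
#' @param hemi_snp_fraction proportion of each parent's emitted calls that are
#'   hemi-SNP artifacts (heterozygous-appearing calls from a duplicated donor
#'   segment, allele frequency uniform on \[0.25, 0.75\]).
#' @param focal_indel_length length in bp of the insertion planted in the
#'   first exon of the focal flowering gene of parent 1.
#' @param go_terms number of GO terms in the annotation table.
#' @param enriched_term_effect multiplier on the coding mutation rate for
#'   genes annotated with the designated enriched term (1 = no enrichment).
#' @param callable_fraction proportion of each chromosome marked callable.
#' @param reverse_strand_fraction proportion of genes placed on the minus
#'   strand.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 200000L,
                       n_genes = 50L,
                       mean_cds_length = 300L,
                       mutation_rate_parent1 = 0.004,
                       mutation_rate_parent2 = 0.004,
                       shared_mutation_rate = 0.002,
                       coding_rate_scale = 0.6,
                       ts_tv_ratio = 2,
                       hemi_snp_fraction = 0.05,
                       focal_indel_length = 5624L,
                       go_terms = 20L,
                       enriched_term_effect = 1,
                       callable_fraction = 0.82,
                       reverse_strand_fraction = 0.3) {
  cfg <- list(seed = as.integer(seed),
              n_chromosomes = as.integer(n_chromosomes),
              chromosome_length = as.integer(chromosome_length),
              n_genes = as.integer(n_genes),
              mean_cds_length = as.integer(mean_cds_length),
              mutation_rate_parent1 = mutation_rate_parent1,
              mutation_rate_parent2 = mutation_rate_parent2,
              shared_mutation_rate = shared_mutation_rate,
              coding_rate_scale = coding_rate_scale,
              ts_tv_ratio = ts_tv_ratio,
              hemi_snp_fraction = hemi_snp_fraction,
              focal_indel_length = as.integer(focal_indel_length),
              go_terms = as.integer(go_terms),
              enriched_term_effect = enriched_term_effect,
              callable_fraction = callable_fraction,
              reverse_strand_fraction = reverse_strand_fraction)
  probs <- c("mutation_rate_parent1", "mutation_rate_parent2",
             "shared_mutation_rate", "coding_rate_scale", "hemi_snp_fraction",
             "callable_fraction", "reverse_strand_fraction")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a probability in [0, 1]", p))
  }
  counts <- c("n_chromosomes", "chromosome_length", "n_genes",
              "mean_cds_length", "go_terms")
  for (p in counts) {
    if (is.na(cfg[[p]]) || cfg[[p]] <= 0L)
      stop(sprintf("'%s' must be a positive count", p))
  }
  if (cfg$focal_indel_length < 0L) stop("'focal_indel_length' must be >= 0")
  if (cfg$ts_tv_ratio <= 0) stop("'ts_tv_ratio' must be positive")
  if (cfg$enriched_term_effect < 0) stop("'enriched_term_effect' must be >= 0")
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")
.TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' @noRd
.revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

## Draw alternate alleles given reference bases and a ts/tv ratio.
.draw_alt <- function(ref, ts_tv_ratio) {
  n <- length(ref)
  if (n == 0L) return(character(0))
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  is_ts <- runif(n) < p_ts
  alt <- unname(.TRANSITION[ref])
  tv <- !is_ts
  if (any(tv)) {
    alt[tv] <- vapply(ref[tv], function(b) {
      pool <- setdiff(.BASES, c(b, .TRANSITION[[b]]))
      pool[sample.int(2L, 1L)]
    }, character(1))
  }
  alt
}

## Fixed vocabulary for term names; the first entries carry the
## flowering / root keywords the candidate screen looks for.
.GO_NAME_POOL <- c(
  "flower development", "floral organ identity", "response to vernalization",
  "root hair elongation", "lateral root development",
  "regulation of flower development", "root system development",
  "response to gibberellin stimulus", "defense response",
  "lipid metabolic process", "photosynthesis light reaction",
  "protein phosphorylation", "ion transmembrane transport",
  "DNA repair", "translation elongation", "cell wall biogenesis",
  "response to osmotic stress", "chromatin remodeling",
  "carbohydrate metabolic process", "vesicle-mediated transport",
  "microtubule-based movement", "RNA splicing", "proteolysis",
  "oxidation-reduction process", "signal transduction")

#' Generate a reference + two-parent genome trio with recorded truth
#'
#' Builds a random reference genome with valid single-transcript gene models
#' (ATG start, in-frame sense codons, terminal stop), plants substitutions in
#' each parent at controlled coding/noncoding rates, adds hemi-SNP artifacts
#' with intermediate allele frequencies from a duplicated donor segment,
#' assigns GO terms (optionally boosting the coding rate of one designated
#' term's genes), marks a callable mask, and plants a large insertion in a
#' focal flowering gene of parent 1. Everything planted is recorded in a
#' truth object so downstream stages can be scored against it.
#'
#' @param config a [sim_config()] object.
#' @return A list with elements `reference` (named [Biostrings::DNAStringSet]),
#'   `models` (gene models; list of `genes` and `exons` data frames),
#'   `calls1`, `calls2` (per-parent variant-call tables),
#'   `callable` (data frame of callable intervals),
#'   `go` (gene_id/term_id annotation table),
#'   `term_names` (term_id/name), `truth` (planted variants, artifact
#'   positions, indel, enriched term), and `config`.
#' @export
simulate_trio <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_chr <- config$n_chromosomes
  L <- config$chromosome_length
  chroms <- sprintf("%s%02d", rep(c("A", "C"), length.out = n_chr),
                    (seq_len(n_chr) + 1L) %/% 2L)

  seqs <- lapply(seq_len(n_chr), function(i) sample(.BASES, L, replace = TRUE))
  names(seqs) <- chroms

  ## ---- gene placement ----
  genes_per_chr <- diff(round(seq(0, config$n_genes, length.out = n_chr + 1L)))
  sense <- .sense_codons()
  stops <- c("TAA", "TAG", "TGA")
  gene_rows <- list(); exon_rows <- list(); gid <- 0L
  for (ci in seq_len(n_chr)) {
    ng <- genes_per_chr[ci]
    if (ng == 0L) next
    cc <- pmax(30L, round(rnorm(ng, config$mean_cds_length,
                                config$mean_cds_length / 4)))
    cds_len <- 3L * cc
    two_exon <- runif(ng) < 0.5
    intron_len <- ifelse(two_exon, sample(80:200, ng, replace = TRUE), 0L)
    footprint <- cds_len + intron_len
    min_gap <- 100L
    if (sum(footprint) + (ng + 1L) * min_gap > L)
      stop(sprintf("chromosome %s too short to host %d genes (need %d bp, have %d)",
                   chroms[ci], ng, sum(footprint) + (ng + 1L) * min_gap, L))
    spare <- L - sum(footprint) - (ng + 1L) * min_gap
    w <- runif(ng + 1L)
    extra <- floor(spare * w / sum(w))
    gaps <- min_gap + extra
    ## cumulative offset of each gene: leading gap, then footprint + gap
    starts <- cumsum(gaps[seq_len(ng)] + c(0L, head(footprint, -1L)))
    strand <- ifelse(runif(ng) < config$reverse_strand_fraction, "-", "+")
    for (g in seq_len(ng)) {
      gid <- gid + 1L
      id <- sprintf("gene%04d", gid)
      codons <- sample(sense, cc[g] - 1L, replace = TRUE)
      codons[1L] <- "ATG"
      cds <- c(unlist(strsplit(codons, "")), unlist(strsplit(sample(stops, 1L), "")))
      gstart <- starts[g] + 1L
      gend <- gstart + footprint[g] - 1L
      gseq <- if (strand[g] == "+") cds else .revcomp_chars(cds)
      if (two_exon[g]) {
        l1 <- sample(seq(30L, cds_len[g] - 30L), 1L)
        b1 <- c(gstart, gstart + l1 - 1L)
        b2 <- c(gstart + l1 + intron_len[g], gend)
        seqs[[ci]][b1[1]:b1[2]] <- gseq[seq_len(l1)]
        seqs[[ci]][b2[1]:b2[2]] <- gseq[(l1 + 1L):cds_len[g]]
        ex <- data.frame(gene_id = id, chromosome = chroms[ci],
                         strand = strand[g],
                         start = c(b1[1], b2[1]), end = c(b1[2], b2[2]),
                         stringsAsFactors = FALSE)
      } else {
        seqs[[ci]][gstart:gend] <- gseq
        ex <- data.frame(gene_id = id, chromosome = chroms[ci],
                         strand = strand[g], start = gstart, end = gend,
                         stringsAsFactors = FALSE)
      }
      ## transcript order: ascending genomic start on +, descending on -
      ex <- ex[order(ex$start, decreasing = (strand[g] == "-")), , drop = FALSE]
      ex$rank <- seq_len(nrow(ex))
      exon_rows[[gid]] <- ex
      gene_rows[[gid]] <- data.frame(gene_id = id, chromosome = chroms[ci],
                                     strand = strand[g], start = gstart,
                                     end = gend, codon_count = cc[g],
                                     stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  exons <- do.call(rbind, exon_rows)
  rownames(genes) <- rownames(exons) <- NULL
  models <- list(genes = genes, exons = exons)

  ## ---- GO annotation ----
  term_ids <- sprintf("GO:%07d", seq_len(config$go_terms))
  term_names <- data.frame(
    term_id = term_ids,
    name = rep_len(.GO_NAME_POOL, config$go_terms),
    stringsAsFactors = FALSE)
  n_terms_per_gene <- 1L + rbinom(nrow(genes), 2L, 0.4)
  go <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    data.frame(gene_id = genes$gene_id[i],
               term_id = sample(term_ids, n_terms_per_gene[i]),
               stringsAsFactors = FALSE)
  }))
  ## designated enriched term: the one whose membership is closest to 10%
  memb <- table(factor(go$term_id, levels = term_ids))
  enriched_term <- term_ids[which.min(abs(as.integer(memb) - round(0.1 * nrow(genes))))]
  enriched_genes <- unique(go$gene_id[go$term_id == enriched_term])

  ## ---- callable mask: drop whole windows to hit the target fraction ----
  n_win <- 50L
  win <- floor(L / n_win)
  n_gap <- round((1 - config$callable_fraction) * n_win)
  callable_rows <- list()
  for (ci in seq_len(n_chr)) {
    gap_idx <- sort(sample.int(n_win, n_gap))
    keep <- setdiff(seq_len(n_win), gap_idx)
    if (length(keep) == 0L) stop("callable_fraction too small: no callable windows")
    st <- (keep - 1L) * win + 1L
    en <- pmin(keep * win, L)
    en[keep == n_win] <- L
    ## merge adjacent windows
    brk <- c(TRUE, st[-1L] != en[-length(en)] + 1L)
    grp <- cumsum(brk)
    callable_rows[[ci]] <- data.frame(
      chromosome = chroms[ci],
      start = tapply(st, grp, min),
      end = tapply(en, grp, max),
      stringsAsFactors = FALSE)
  }
  callable <- do.call(rbind, callable_rows)
  rownames(callable) <- NULL

  .callable_at <- function(chrom, pos) {
    cc <- callable[callable$chromosome == chrom, , drop = FALSE]
    idx <- findInterval(pos, cc$start)
    idx > 0L & pos <= cc$end[pmax(idx, 1L)]
  }

  ## ---- mutation planting ----
  exon_mask <- lapply(chroms, function(ch) {
    m <- integer(0)
    ex <- exons[exons$chromosome == ch, , drop = FALSE]
    if (nrow(ex)) m <- unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE))
    m
  })
  names(exon_mask) <- chroms
  enriched_mask <- lapply(chroms, function(ch) {
    ex <- exons[exons$chromosome == ch & exons$gene_id %in% enriched_genes, , drop = FALSE]
    if (nrow(ex)) unlist(mapply(seq.int, ex$start, ex$end, SIMPLIFY = FALSE)) else integer(0)
  })
  names(enriched_mask) <- chroms

  .plant <- function(rate, exclude) {
    out <- list()
    for (ci in seq_len(n_chr)) {
      ch <- chroms[ci]
      rv <- rep(rate, L)
      rv[exon_mask[[ch]]] <- rate * config$coding_rate_scale
      if (config$enriched_term_effect != 1 && length(enriched_mask[[ch]]))
        rv[enriched_mask[[ch]]] <- pmin(1, rate * config$coding_rate_scale *
                                          config$enriched_term_effect)
      pos <- which(runif(L) < rv)
      pos <- pos[.callable_at(ch, pos)]
      if (!is.null(exclude[[ch]])) pos <- setdiff(pos, exclude[[ch]])
      if (length(pos) == 0L) { out[[ch]] <- NULL; next }
      ref <- seqs[[ci]][pos]
      out[[ch]] <- data.frame(chromosome = ch, position = pos,
                              ref_allele = ref,
                              alt_allele = .draw_alt(ref, config$ts_tv_ratio),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  }

  shared <- .plant(config$shared_mutation_rate, list())
  used <- if (is.null(shared)) list() else split(shared$position, shared$chromosome)
  p1 <- .plant(config$mutation_rate_parent1, used)
  used2 <- used
  if (!is.null(p1)) {
    for (ch in unique(p1$chromosome))
      used2[[ch]] <- c(used2[[ch]], p1$position[p1$chromosome == ch])
  }
  p2 <- .plant(config$mutation_rate_parent2, used2)

  ## ---- truth effect classes via whole-protein rebuild ----
  .truth_effect <- function(chrom, pos, alt) {
    ex <- exons[exons$chromosome == chrom & exons$start <= pos & exons$end >= pos, , drop = FALSE]
    if (nrow(ex) == 0L) return("noncoding")
    ex1 <- ex[1L, ]  # genes do not overlap by construction
    gex <- exons[exons$gene_id == ex1$gene_id, , drop = FALSE]
    gex <- gex[order(gex$start), , drop = FALSE]
    ci <- match(chrom, chroms)
    cds_ref <- unlist(mapply(function(s, e) seqs[[ci]][s:e], gex$start, gex$end,
                             SIMPLIFY = FALSE))
    cds_alt <- cds_ref
    offsets <- cumsum(c(0L, gex$end - gex$start + 1L))
    k <- which(gex$start <= pos & gex$end >= pos)
    cds_alt[offsets[k] + pos - gex$start[k] + 1L] <- alt
    if (ex1$strand == "-") {
      cds_ref <- .revcomp_chars(cds_ref); cds_alt <- .revcomp_chars(cds_alt)
    }
    pr <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cds_ref, collapse = "")), no.init.codon = TRUE))
    pa <- as.character(Biostrings::translate(
      Biostrings::DNAString(paste(cds_alt, collapse = "")), no.init.codon = TRUE))
    if (pr == pa) "synonymous" else "nonsynonymous"
  }

  .with_truth <- function(df, parent_label) {
    if (is.null(df) || nrow(df) == 0L) return(NULL)
    df$parent <- parent_label
    df$effect_class <- vapply(seq_len(nrow(df)), function(i)
      .truth_effect(df$chromosome[i], df$position[i], df$alt_allele[i]),
      character(1))
    df
  }
  shared <- .with_truth(shared, "both")
  p1 <- .with_truth(p1, "parent1")
  p2 <- .with_truth(p2, "parent2")
  planted <- rbind(shared, p1, p2)
  if (is.null(planted))
    planted <- data.frame(chromosome = character(0), position = integer(0),
                          ref_allele = character(0), alt_allele = character(0),
                          parent = character(0), effect_class = character(0))

  ## ---- evidence columns + hemi artifacts ----
  .evidence <- function(df) {
    n <- nrow(df)
    df$quality <- round(runif(n, 35, 60), 1)
    df$depth <- rpois(n, 25) + 5L
    df$alt_frequency <- rep(1, n)
    df$prob_not_ref <- round(runif(n, 0.95, 1), 4)
    df
  }
  .hemi <- function(n_hemi, parent_label) {
    if (n_hemi == 0L) return(NULL)
    ## artifacts cluster in one duplicated donor segment per chromosome
    per <- diff(round(seq(0, n_hemi, length.out = n_chr + 1L)))
    out <- list()
    for (ci in seq_len(n_chr)) {
      if (per[ci] == 0L) next
      seg_len <- min(20000L, L)
      seg_start <- sample.int(L - seg_len + 1L, 1L)
      pos <- sort(sample(seq(seg_start, seg_start + seg_len - 1L), per[ci]))
      pos <- pos[.callable_at(chroms[ci], pos)]
      pos <- setdiff(pos, planted$position[planted$chromosome == chroms[ci]])
      if (length(pos) == 0L) next
      ref <- seqs[[ci]][pos]
      d <- data.frame(chromosome = chroms[ci], position = pos,
                      ref_allele = ref,
                      alt_allele = .draw_alt(ref, config$ts_tv_ratio),
                      parent = parent_label, stringsAsFactors = FALSE)
      d$quality <- round(runif(nrow(d), 35, 60), 1)
      d$depth <- rpois(nrow(d), 25) + 5L
      d$alt_frequency <- round(runif(nrow(d), 0.25, 0.75), 3)
      d$prob_not_ref <- round(runif(nrow(d), 0.95, 1), 4)
      out[[ci]] <- d
    }
    if (length(out) == 0L) return(NULL)
    do.call(rbind, out)
  }

  ## artifacts come from duplicated segments, so their number tracks the
  ## two-parent average divergence, not each parent's own rate
  .own_calls <- function(parent_label) {
    own <- planted[planted$parent %in% c("both", parent_label), , drop = FALSE]
    own <- own[, c("chromosome", "position", "ref_allele", "alt_allele", "parent")]
    own$parent <- rep(parent_label, nrow(own))
    .evidence(own)
  }
  own1 <- .own_calls("parent1")
  own2 <- .own_calls("parent2")
  f <- config$hemi_snp_fraction
  n_hemi <- round(f / (1 - f) * (nrow(own1) + nrow(own2)) / 2)
  .calls_for <- function(own, parent_label) {
    calls <- rbind(own, .hemi(n_hemi, parent_label))
    calls <- calls[order(calls$chromosome, calls$position), , drop = FALSE]
    rownames(calls) <- NULL
    calls
  }
  calls1 <- .calls_for(own1, "parent1")
  calls2 <- .calls_for(own2, "parent2")

  ## ---- focal indel in a flowering gene of parent 1 ----
  flower_terms <- term_names$term_id[grepl("flower|floral|vernalization",
                                           term_names$name)]
  cand <- unique(go$gene_id[go$term_id %in% flower_terms])
  focal_gene <- if (length(cand)) sort(cand)[1L] else genes$gene_id[1L]
  fex <- exons[exons$gene_id == focal_gene & exons$rank == 1L, , drop = FALSE]
  indel_pos <- fex$start + ((fex$end - fex$start) %/% 2L)
  planted_indel <- list(gene_id = focal_gene, position = as.integer(indel_pos),
                        length = config$focal_indel_length, parent = "parent1")

  reference <- Biostrings::DNAStringSet(
    vapply(seqs, paste, character(1), collapse = ""))
  names(reference) <- chroms

  truth <- list(planted_variants = planted,
                hemi_positions = rbind(
                  if (any(calls1$alt_frequency < 1))
                    data.frame(parent = "parent1",
                               chromosome = calls1$chromosome[calls1$alt_frequency < 1],
                               position = calls1$position[calls1$alt_frequency < 1]),
                  if (any(calls2$alt_frequency < 1))
                    data.frame(parent = "parent2",
                               chromosome = calls2$chromosome[calls2$alt_frequency < 1],
                               position = calls2$position[calls2$alt_frequency < 1])),
                planted_indel = planted_indel,
                enriched_term = enriched_term,
                focal_gene = focal_gene)

  list(reference = reference, models = models, calls1 = calls1,
       calls2 = calls2, callable = callable, go = go,
       term_names = term_names, truth = truth, config = config)
}

#' Simulate a per-gene nonsynonymous load table with one enriched GO term
#'
#' Lightweight generator for the GO enrichment machinery: per-gene codon
#' counts and Poisson nonsynonymous SNP counts, a term annotation table, and
#' optionally one designated term whose genes carry an elevated rate.
#'
#' @param n_genes number of genes.
#' @param n_terms number of GO terms.
#' @param mean_codons mean codon count per gene.
#' @param rate_ns_per_codon baseline expected nonsynonymous SNPs per codon
#'   (default matches a nonsynonymous density of about 0.075% per bp).
#' @param enriched_term_effect rate multiplier for genes of the planted term
#'   (1 = null table, no planted term).
#' @param n_enriched_genes number of genes annotated with the planted term.
#' @param seed integer seed.
#' @return list with `loads` (gene_id, ns_snp_count, codon_count),
#'   `annotations` (gene_id, term_id), and `enriched_term` (NA for null
#'   tables).
#' @export
simulate_gene_loads <- function(n_genes = 500L, n_terms = 50L,
                                mean_codons = 300L,
                                rate_ns_per_codon = 0.00225,
                                enriched_term_effect = 1,
                                n_enriched_genes = 20L,
                                seed = 1L) {
  stopifnot(n_genes >= 2L, n_terms >= 1L, rate_ns_per_codon >= 0)
  set.seed(seed)
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  codons <- pmax(30L, round(rnorm(n_genes, mean_codons, mean_codons / 3)))
  rate <- rep(rate_ns_per_codon, n_genes)
  term_ids <- sprintf("GO:%07d", seq_len(n_terms))
  ann <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
    m <- sample(10:40, 1L)
    data.frame(gene_id = sample(gene_ids, min(m, n_genes)),
               term_id = term_ids[i], stringsAsFactors = FALSE)
  }))
  enriched_term <- NA_character_
  if (enriched_term_effect != 1) {
    enriched_term <- term_ids[1L]
    chosen <- sample(gene_ids, n_enriched_genes)
    ann <- ann[ann$term_id != enriched_term, , drop = FALSE]
    ann <- rbind(ann, data.frame(gene_id = chosen, term_id = enriched_term,
                                 stringsAsFactors = FALSE))
    rate[gene_ids %in% chosen] <- rate_ns_per_codon * enriched_term_effect
  }
  loads <- data.frame(gene_id = gene_ids,
                      ns_snp_count = rpois(n_genes, codons * rate),
                      codon_count = codons, stringsAsFactors = FALSE)
  rownames(ann) <- NULL
  list(loads = loads, annotations = ann, enriched_term = enriched_term)
}

#' Simulate a doubled-haploid mapping population
#'
#' Genotypes are coded 0/1 and generated along each chromosome as a Markov
#' chain whose adjacent-marker recombination fractions come from the inverse
#' Kosambi function of the map distance. Phenotype is the sum of planted
#' additive QTL effects plus Gaussian noise scaled to the requested
#' narrow-sense heritability (expected genetic variance of a 0/1 DH locus
#' with effect a is a^2/4).
#'
#' @param n_lines number of DH lines.
#' @param map data frame with columns `marker`, `chromosome`, `pos_cM`
#'   (strictly increasing within chromosome).
#' @param qtl data frame with columns `chromosome`, `pos_cM`, `effect`
#'   (phenotype difference between the two genotype classes); NULL for a null
#'   population.
#' @param heritability proportion of phenotypic variance explained by the
#'   planted QTL, in \[0, 1\]. With no QTL (or heritability 0) the phenotype
#'   is standard-normal noise.
#' @param seed integer seed.
#' @param missing_rate proportion of genotype cells set missing (NA).
#' @return list of class `"dh_population"` with `map`, `genotypes`
#'   (n_lines x n_markers 0/1 matrix), `phenotype`, and `qtl`.
#' @export
simulate_dh_population <- function(n_lines, map, qtl = NULL,
                                   heritability = 0.5, seed = 1L,
                                   missing_rate = 0) {
  stopifnot(is.data.frame(map),
            all(c("marker", "chromosome", "pos_cM") %in% names(map)),
            n_lines >= 2L, heritability >= 0, heritability <= 1,
            missing_rate >= 0, missing_rate < 1)
  for (ch in unique(map$chromosome)) {
    p <- map$pos_cM[map$chromosome == ch]
    if (any(diff(p) <= 0) && any(diff(p) < 0))
      stop("marker map must be non-decreasing within chromosome")
  }
  if (!is.null(qtl)) {
    stopifnot(all(c("chromosome", "pos_cM", "effect") %in% names(qtl)))
    for (i in seq_len(nrow(qtl))) {
      p <- map$pos_cM[map$chromosome == qtl$chromosome[i]]
      if (length(p) == 0L || qtl$pos_cM[i] < min(p) || qtl$pos_cM[i] > max(p))
        stop("QTL position outside the map span of its chromosome")
    }
  }
  set.seed(seed)
  map <- map[order(match(map$chromosome, unique(map$chromosome)), map$pos_cM), ,
             drop = FALSE]
  ## augment with QTL pseudo-loci so their genotypes are simulated exactly
  aug <- map[, c("marker", "chromosome", "pos_cM")]
  aug$is_qtl <- FALSE
  if (!is.null(qtl) && nrow(qtl)) {
    qaug <- data.frame(marker = sprintf(".qtl%02d", seq_len(nrow(qtl))),
                       chromosome = qtl$chromosome, pos_cM = qtl$pos_cM,
                       is_qtl = TRUE, stringsAsFactors = FALSE)
    aug <- rbind(aug, qaug)
    aug <- aug[order(match(aug$chromosome, unique(map$chromosome)),
                     aug$pos_cM, aug$is_qtl), , drop = FALSE]
  }
  G <- matrix(NA_integer_, n_lines, nrow(aug))
  colnames(G) <- aug$marker
  for (ch in unique(aug$chromosome)) {
    idx <- which(aug$chromosome == ch)
    pos <- aug$pos_cM[idx]
    g <- matrix(NA_integer_, n_lines, length(idx))
    g[, 1L] <- rbinom(n_lines, 1L, 0.5)
    if (length(idx) > 1L) {
      r <- kosambi_to_r(diff(pos))
      for (j in 2L:length(idx)) {
        flip <- rbinom(n_lines, 1L, r[j - 1L])
        g[, j] <- bitwXor(g[, j - 1L], flip)
      }
    }
    G[, idx] <- g
  }
  genetic <- rep(0, n_lines)
  if (!is.null(qtl) && nrow(qtl)) {
    qcols <- match(sprintf(".qtl%02d", seq_len(nrow(qtl))), colnames(G))
    for (i in seq_len(nrow(qtl)))
      genetic <- genetic + qtl$effect[i] * G[, qcols[i]]
  }
  var_g <- if (is.null(qtl) || nrow(qtl) == 0L) 0 else sum(qtl$effect^2) / 4
  if (heritability == 0 || var_g == 0) {
    phenotype <- rnorm(n_lines, 0, 1)
    if (heritability > 0 && var_g == 0) phenotype <- genetic + phenotype
  } else if (heritability == 1) {
    phenotype <- genetic
  } else {
    var_e <- var_g * (1 - heritability) / heritability
    phenotype <- genetic + rnorm(n_lines, 0, sqrt(var_e))
  }
  keep <- !grepl("^\\.qtl", colnames(G))
  G <- G[, keep, drop = FALSE]
  aug <- aug[keep, , drop = FALSE]
  if (missing_rate > 0) {
    nm <- round(missing_rate * length(G))
    if (nm > 0) G[sample.int(length(G), nm)] <- NA_integer_
  }
  out <- list(map = data.frame(marker = aug$marker, chromosome = aug$chromosome,
                               pos_cM = aug$pos_cM, stringsAsFactors = FALSE),
              genotypes = G, phenotype = phenotype, qtl = qtl)
  class(out) <- "dh_population"
  out
}
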
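# Independent oracles for the computational cores. They deliberately avoid
# the package's code paths: translation goes through seqinr, set algebra and
# alignment scanning are naive loops.

.ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_translate <- function(chars) {
  paste(seqinr::translate(tolower(chars)), collapse = "")
}

# Effect class by rebuilding and translating the complete mutant CDS.
oracle_effect <- function(cds_ref_chars, cds_alt_chars) {
  if (oracle_translate(cds_ref_chars) == oracle_translate(cds_alt_chars))
    "synonymous" else "nonsynonymous"
}

# Nei-Gojobori expected sites for one codon (seqinr translation).
oracle_ng_sites <- function(codon) {
  chars <- strsplit(codon, "")[[1]]
  aa <- seqinr::translate(tolower(chars))
  syn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[p])) {
      mut <- chars
      mut[p] <- b
      if (seqinr::translate(tolower(mut)) == aa) syn <- syn + 1 / 3
    }
  }
  c(syn = syn, nonsyn = 3 - syn)
}

# Pathway-enumeration substitution counts between two codons: walk every
# ordering of the differing positions, drop orderings passing through an
# intermediate stop unless all do, average.
oracle_ng_subs <- function(ref_codon, alt_codon) {
  rc <- strsplit(ref_codon, "")[[1]]
  ac <- strsplit(alt_codon, "")[[1]]
  d <- which(rc != ac)
  if (length(d) == 0) return(c(syn = 0, nonsyn = 0))
  orders <- if (length(d) == 1) list(d) else {
    perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    perms(d)
  }
  walk <- function(ord) {
    cur <- rc; syn <- 0; nonsyn <- 0; valid <- TRUE
    for (k in seq_along(ord)) {
      nxt <- cur
      nxt[ord[k]] <- ac[ord[k]]
      a1 <- seqinr::translate(tolower(cur))
      a2 <- seqinr::translate(tolower(nxt))
      if (a1 == a2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      if (k < length(ord) && a2 == "*") valid <- FALSE
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, valid = valid)
  }
  res <- lapply(orders, walk)
  ok <- vapply(res, function(x) x$valid, logical(1))
  use <- if (any(ok)) res[ok] else res
  c(syn = mean(vapply(use, function(x) x$syn, numeric(1))),
    nonsyn = mean(vapply(use, function(x) x$nonsyn, numeric(1))))
}

# Brute-force three-list comparison over key strings.
oracle_compare_keys <- function(k1, k2) {
  shared <- character(0); p1 <- character(0); p2 <- character(0)
  for (k in k1) if (k %in% k2) shared <- c(shared, k) else p1 <- c(p1, k)
  for (k in k2) if (!(k %in% k1)) p2 <- c(p2, k)
  list(shared = sort(shared), p1_only = sort(p1), p2_only = sort(p2),
       poly = sort(c(p1, p2)))
}

# Naive sliding-window hit count: every start position on either strand with
# at most max_edit mismatches.
oracle_sliding_hits <- function(read, genome_str, max_edit) {
  rchars <- strsplit(read, "")[[1]]
  rc <- rev(unname(.ORACLE_COMP[rchars]))
  hits <- 0L
  for (g in genome_str) {
    gchars <- strsplit(g, "")[[1]]
    L <- length(gchars); w <- length(rchars)
    if (w > L) next
    for (s in 1:(L - w + 1)) {
      win <- gchars[s:(s + w - 1)]
      if (sum(win != rchars) <= max_edit || sum(win != rc) <= max_edit)
        hits <- hits + 1L
    }
  }
  hits
}

# Closed-form single-marker regression LOD via lm().
oracle_marker_lod <- function(g, y) {
  rss0 <- sum((y - mean(y))^2)
  rss1 <- sum(residuals(lm(y ~ g))^2)
  (length(y) / 2) * log10(rss0 / rss1)
}

# Quick builder for handmade call rows.
make_call <- function(chromosome = "A01", position = 100L, ref = "A",
                      alt = "G", quality = 40, depth = 20,
                      alt_frequency = 1, prob_not_ref = 0.99,
                      parent = "parent1") {
  data.frame(chromosome = chromosome, position = as.integer(position),
             ref_allele = ref, alt_allele = alt, quality = quality,
             depth = depth, alt_frequency = alt_frequency,
             prob_not_ref = prob_not_ref, parent = parent,
             stringsAsFactors = FALSE)
}

# A single-gene fixture: the chromosome is exactly one forward- or
# reverse-strand gene, given as codons (start/stop included by the caller).
single_gene_fixture <- function(codons, strand = "+", chromosome = "A01") {
  cds <- paste(codons, collapse = "")
  chars <- strsplit(cds, "")[[1]]
  gseq <- if (strand == "+") cds else
    paste(rev(unname(.ORACLE_COMP[chars])), collapse = "")
  reference <- Biostrings::DNAStringSet(gseq)
  names(reference) <- chromosome
  L <- nchar(cds)
  models <- list(
    genes = data.frame(gene_id = "g1", chromosome = chromosome,
                       strand = strand, start = 1L, end = L,
                       codon_count = L %/% 3L, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "g1", chromosome = chromosome,
                       strand = strand, start = 1L, end = L, rank = 1L,
                       stringsAsFactors = FALSE))
  list(reference = reference, models = models)
}

# Small cached trio so several test files can share one simulation.
small_trio <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_trio(sim_config(seed = 421, n_chromosomes = 2,
                                         chromosome_length = 120000,
                                         n_genes = 30))
    cache
  }
})

# Standard pipeline front end: filter, hemi-clean, compare.
pipeline_compare <- function(trio) {
  c1 <- flag_hemi_snps(filter_calls(trio$calls1))$clean
  c2 <- flag_hemi_snps(filter_calls(trio$calls2))$clean
  compare_parents(c1, c2)
}
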
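test_that("codon-level classification follows the genetic code", {
  fx <- single_gene_fixture(c("ATG", "GCT", "AAA", "TGG", "TAA"))
  ## third-position GCT -> GCC: Ala -> Ala
  syn <- classify_effects(make_call(position = 6, ref = "T", alt = "C"),
                          fx$models, fx$reference)
  expect_equal(syn$effect, "synonymous")
  expect_equal(syn$ref_aa, "A")
  ## first-position GCT -> CCT: Ala -> Pro
  ns <- classify_effects(make_call(position = 4, ref = "G", alt = "C"),
                         fx$models, fx$reference)
  expect_equal(ns$effect, "nonsynonymous")
  expect_equal(ns$alt_aa, "P")
})

test_that("calls outside every CDS are noncoding", {
  trio <- small_trio()
  exons <- trio$models$exons
  chrom <- exons$chromosome[1]
  pos <- min(exons$start[exons$chromosome == chrom]) - 500L
  ref <- as.character(Biostrings::subseq(trio$reference[[chrom]], pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  out <- classify_effects(make_call(chromosome = chrom, position = pos,
                                    ref = ref, alt = alt),
                          trio$models, trio$reference)
  expect_equal(out$effect, "noncoding")
  expect_true(is.na(out$gene_id))
})

test_that("a reference-allele mismatch is an error", {
  fx <- single_gene_fixture(c("ATG", "GCT", "TAA"))
  wrong <- setdiff(c("A", "C", "G", "T"),
                   c("G", as.character(Biostrings::subseq(fx$reference[[1]], 4, 4))))[1]
  expect_error(classify_effects(make_call(position = 4, ref = wrong, alt = "G"),
                                fx$models, fx$reference),
               "reference mismatch")
})

test_that("classification matches the full-translation oracle on planted SNPs", {
  trio <- small_trio()
  planted <- trio$truth$planted_variants
  coding <- planted[planted$effect_class != "noncoding", ]
  calls <- data.frame(chromosome = coding$chromosome, position = coding$position,
                      ref_allele = coding$ref_allele,
                      alt_allele = coding$alt_allele, stringsAsFactors = FALSE)
  classified <- classify_effects(calls, trio$models, trio$reference)
  classified <- classified[!is.na(classified$gene_id), ]
  exons <- trio$models$exons
  genes <- trio$models$genes
  for (i in seq_len(nrow(classified))) {
    id <- classified$gene_id[i]
    gex <- exons[exons$gene_id == id, ]
    gex <- gex[order(gex$start), ]
    strand <- genes$strand[genes$gene_id == id]
    chrom <- classified$chromosome[i]
    cds_ref <- unlist(lapply(seq_len(nrow(gex)), function(e)
      strsplit(as.character(Biostrings::subseq(
        trio$reference[[chrom]], gex$start[e], gex$end[e])), "")[[1]]))
    offs <- cumsum(c(0, gex$end - gex$start + 1))
    k <- which(gex$start <= classified$position[i] & gex$end >= classified$position[i])
    cds_alt <- cds_ref
    cds_alt[offs[k] + classified$position[i] - gex$start[k] + 1] <-
      classified$alt_allele[i]
    if (strand == "-") {
      cds_ref <- rev(unname(.ORACLE_COMP[cds_ref]))
      cds_alt <- rev(unname(.ORACLE_COMP[cds_alt]))
    }
    expect_equal(classified$effect[i], oracle_effect(cds_ref, cds_alt),
                 info = sprintf("%s %s:%d", id, chrom, classified$position[i]))
  }
})

test_that("classification recovers the planted effect classes exactly", {
  trio <- small_trio()
  planted <- trio$truth$planted_variants
  calls <- data.frame(chromosome = planted$chromosome,
                      position = planted$position,
                      ref_allele = planted$ref_allele,
                      alt_allele = planted$alt_allele, stringsAsFactors = FALSE)
  got <- call_effect_classes(classify_effects(calls, trio$models, trio$reference))
  key <- paste(got$chromosome, got$position, got$alt_allele)
  want <- setNames(planted$effect_class,
                   paste(planted$chromosome, planted$position, planted$alt_allele))
  expect_identical(got$effect, unname(want[key]))
})

test_that("classification is invariant under chromosome reverse-complement", {
  fx <- single_gene_fixture(c("ATG", "GAT", "CGA", "TGG", "TAA"), strand = "+")
  L <- Biostrings::width(fx$reference)[1]
  mirror_ref <- Biostrings::reverseComplement(fx$reference[[1]])
  mirror <- fx
  mirror$reference <- Biostrings::DNAStringSet(mirror_ref)
  names(mirror$reference) <- names(fx$reference)
  mirror$models$genes$strand <- "-"
  mirror$models$exons$strand <- "-"
  for (pos in 4:12) {
    ref <- as.character(Biostrings::subseq(fx$reference[[1]], pos, pos))
    for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
      fwd <- classify_effects(make_call(position = pos, ref = ref, alt = alt),
                              fx$models, fx$reference)
      mpos <- L - pos + 1L
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      rev_call <- make_call(position = mpos, ref = unname(comp[ref]),
                            alt = unname(comp[alt]))
      bwd <- classify_effects(rev_call, mirror$models, mirror$reference)
      expect_identical(fwd$effect, bwd$effect)
      expect_identical(fwd$ref_codon, bwd$ref_codon)
    }
  }
})

test_that("density arithmetic and category conservation hold", {
  callable <- data.frame(chromosome = "A01", start = 1, end = 5000)
  calls <- do.call(rbind, lapply(1:10, function(i) make_call(position = i * 100)))
  calls$effect <- rep(c("noncoding", "synonymous", "nonsynonymous"),
                      length.out = 10)
  d <- compute_density(calls, callable)
  expect_equal(d$density[d$category == "total"], 0.2)  # 10 / 5000 as percent
  expect_equal(sum(d$snp_count[d$category != "total"]),
               d$snp_count[d$category == "total"])
  ## empty call set: all densities zero
  d0 <- compute_density(calls[0, ], callable)
  expect_true(all(d0$density == 0))
  ## calls on an uncovered chromosome are an error
  bad <- calls
  bad$chromosome <- "Z99"
  expect_error(compute_density(bad, callable), "zero callable length")
})

test_that("pipeline densities recover the planted rate within binomial bounds", {
  cfg <- sim_config(seed = 77, n_chromosomes = 2, chromosome_length = 400000,
                    n_genes = 30, mutation_rate_parent1 = 0.0025,
                    mutation_rate_parent2 = 0, shared_mutation_rate = 0,
                    coding_rate_scale = 1, hemi_snp_fraction = 0.05)
  trio <- simulate_trio(cfg)
  clean <- flag_hemi_snps(filter_calls(trio$calls1))$clean
  classified <- call_effect_classes(
    classify_effects(clean, trio$models, trio$reference))
  d <- compute_density(classified, trio$callable)
  total_count <- sum(d$snp_count[d$category == "total"])
  n_callable <- sum(d$callable_length[d$category == "total"])
  bounds <- qbinom(c(0.005, 0.995), n_callable, 0.0025)
  expect_gte(total_count, bounds[1])
  expect_lte(total_count, bounds[2])
})

test_that("genome density comparison matches the longhand Welch formula", {
  set.seed(5)
  a <- rnorm(10, 0.25, 0.04)
  c_ <- rnorm(9, 0.17, 0.07)
  got <- compare_genome_densities(a, c_)
  sa2 <- var(a) / length(a)
  sc2 <- var(c_) / length(c_)
  t_hand <- (mean(a) - mean(c_)) / sqrt(sa2 + sc2)
  df_hand <- (sa2 + sc2)^2 / (sa2^2 / (length(a) - 1) + sc2^2 / (length(c_) - 1))
  p_hand <- 2 * pt(-abs(t_hand), df_hand)
  expect_equal(got$statistic, t_hand, tolerance = 1e-12)
  expect_equal(got$df, df_hand, tolerance = 1e-9)
  expect_equal(got$p_value, p_hand, tolerance = 1e-12)
  ## identical lists: no difference
  same <- compare_genome_densities(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  ## forced separation
  sep <- compare_genome_densities(c(2, 2, 2) + 1e-9 * (1:3),
                                  c(1, 1, 1) + 1e-9 * (1:3))
  expect_lt(sep$p_value, 0.01)
  expect_error(compare_genome_densities(1, c(1, 2)), "at least 2")
})

test_that("equal-divergence chi-square reproduces the published arithmetic", {
  res <- equal_divergence_test(355048, 789793)
  expect_equal(res$expected, 572420.5)
  expect_lt(res$p_value, 1e-4)
  ## cross-check statistic and p against stats::chisq.test
  ct <- suppressWarnings(chisq.test(c(355048, 789793), p = c(0.5, 0.5)))
  expect_equal(res$statistic, unname(ct$statistic), tolerance = 1e-12)
  perfect <- equal_divergence_test(10, 10)
  expect_equal(perfect$statistic, 0)
  expect_equal(perfect$p_value, 1)
  skewed <- equal_divergence_test(0, 20)
  expect_equal(skewed$statistic, 20)
  expect_equal(skewed$p_value, pchisq(20, 1, lower.tail = FALSE))
  expect_equal(skewed$p_value, 7.7e-6, tolerance = 0.01)
  expect_error(equal_divergence_test(-1, 5), "non-negative")
  expect_error(equal_divergence_test(0, 0), "not both be zero")
})
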
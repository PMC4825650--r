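test_that("a variant-free gene has zero substitutions and zero rates", {
  fx <- single_gene_fixture(c("ATG", "AAA", "TGG", "TAA"))
  rec <- gene_dnds("g1", fx$models, fx$reference, NULL)
  expect_equal(rec$n_subs, 0)
  expect_equal(rec$s_subs, 0)
  expect_equal(rec$dN, 0)
  expect_equal(rec$dS, 0)
  ## sites cover the three counted codons (terminal stop excluded)
  expect_equal(rec$n_sites + rec$s_sites, 9)
})

test_that("a synonymous Lys codon change is counted as one synonymous sub", {
  fx <- single_gene_fixture(c("ATG", "AAA", "TGG", "TAA"))
  ## AAA -> AAG at position 6: Lys -> Lys
  rec <- gene_dnds("g1", fx$models, fx$reference,
                   make_call(position = 6, ref = "A", alt = "G"))
  expect_equal(rec$s_subs, 1)
  expect_equal(rec$n_subs, 0)
  expect_equal(rec$dN, 0)
  expect_gt(rec$dS, 0)
  expect_equal(aggregate_dnds(rec), 0)
})

test_that("counting matches the pathway-enumeration oracle on random genes", {
  set.seed(17)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  for (g in 1:50) {
    n_codon <- sample(8:20, 1)
    codons <- c("ATG", sample(sense, n_codon - 2, replace = TRUE), "TAA")
    strand <- sample(c("+", "-"), 1)
    fx <- single_gene_fixture(codons, strand = strand)
    ## plant 1-2 SNPs, sometimes in the same codon, never in ATG/stop
    n_var <- sample(1:2, 1)
    cds_pos <- if (n_var == 2 && runif(1) < 0.5) {
      ci <- sample(2:(n_codon - 1), 1)
      sample(3 * (ci - 1) + 1:3, 2)
    } else sample(4:(3 * (n_codon - 1)), n_var)
    cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
    alt_cds <- cds
    for (tp in cds_pos)
      alt_cds[tp] <- sample(setdiff(c("A", "C", "G", "T"), cds[tp]), 1)
    ## skip cases where the mutation creates a premature stop (handled below)
    mut_codons <- apply(matrix(alt_cds, nrow = 3), 2, paste, collapse = "")
    if (any(mut_codons[-length(mut_codons)] %in% c("TAA", "TAG", "TGA"))) next
    L <- length(cds)
    calls <- do.call(rbind, lapply(cds_pos, function(tp) {
      gpos <- if (strand == "+") tp else L - tp + 1L
      make_call(position = gpos,
                ref = as.character(Biostrings::subseq(fx$reference[[1]], gpos, gpos)),
                alt = if (strand == "+") alt_cds[tp]
                      else unname(.ORACLE_COMP[alt_cds[tp]]))
    }))
    rec <- gene_dnds("g1", fx$models, fx$reference, calls)
    ## oracle: per-codon sites averaged over both sequences + pathway subs
    ref_codons <- apply(matrix(cds, nrow = 3), 2, paste, collapse = "")
    o_s_sites <- o_n_sites <- o_s_subs <- o_n_subs <- 0
    for (k in seq_len(n_codon - 1)) {
      sr <- oracle_ng_sites(ref_codons[k])
      sm <- oracle_ng_sites(mut_codons[k])
      o_s_sites <- o_s_sites + (sr["syn"] + sm["syn"]) / 2
      o_n_sites <- o_n_sites + (sr["nonsyn"] + sm["nonsyn"]) / 2
      subs <- oracle_ng_subs(ref_codons[k], mut_codons[k])
      o_s_subs <- o_s_subs + subs["syn"]
      o_n_subs <- o_n_subs + subs["nonsyn"]
    }
    expect_equal(rec$s_sites, unname(o_s_sites), tolerance = 1e-12)
    expect_equal(rec$n_sites, unname(o_n_sites), tolerance = 1e-12)
    expect_equal(rec$s_subs, unname(o_s_subs), tolerance = 1e-12)
    expect_equal(rec$n_subs, unname(o_n_subs), tolerance = 1e-12)
  }
})

test_that("a premature stop flags the record and drops the codon", {
  ## TGG -> TGA (position 6, G -> A) creates an internal stop
  fx <- single_gene_fixture(c("ATG", "TGG", "AAA", "TAA"))
  rec <- gene_dnds("g1", fx$models, fx$reference,
                   make_call(position = 6, ref = "G", alt = "A"))
  expect_true(rec$premature_stop)
  expect_equal(rec$n_subs + rec$s_subs, 0)
  ## sites cover only the two untouched codons
  expect_equal(rec$n_sites + rec$s_sites, 6)
})

test_that("variants outside the CDS are rejected", {
  fx <- single_gene_fixture(c("ATG", "AAA", "TAA"))
  expect_error(gene_dnds("g1", fx$models, fx$reference,
                         make_call(position = 400, ref = "A", alt = "G")),
               "outside the CDS")
})

test_that("aggregate ratio behaves as a ratio of means", {
  recs <- data.frame(dN = c(0.02, 0.01), dS = c(0.02, 0.01))
  expect_equal(aggregate_dnds(recs), 1)
  expect_equal(aggregate_dnds(data.frame(dN = 0.02, dS = 0.04)), 0.5)
  ## invariant under duplication of the record set
  trio <- small_trio()
  cmp <- pipeline_compare(trio)
  cl <- classify_effects(cmp$polymorphic_between_parents, trio$models,
                         trio$reference)
  recs2 <- dnds_table(cl, trio$models, trio$reference)
  expect_equal(aggregate_dnds(rbind(recs2, recs2)), aggregate_dnds(recs2))
  expect_error(aggregate_dnds(data.frame(dN = c(0, 0), dS = c(0, 0))),
               "mean dS is zero")
})

test_that("a purifying regime yields an aggregate ratio below one", {
  set.seed(23)
  below <- vapply(1:50, function(i) {
    n_genes <- 80
    s_sites <- runif(n_genes, 150, 250)
    n_sites <- s_sites * 3
    p <- 0.02
    recs <- data.frame(dN = rpois(n_genes, n_sites * p / 4) / n_sites,
                       dS = rpois(n_genes, s_sites * p) / s_sites)
    aggregate_dnds(recs) < 1
  }, logical(1))
  expect_true(all(below))
})

test_that("bootstrap CI is seed-reproducible and degenerate on constant data", {
  recs <- data.frame(dN = rep(0.01, 10), dS = rep(0.02, 10))
  ci <- bootstrap_dnds_ci(recs, n_boot = 500, seed = 3)
  expect_equal(ci$lower, 0.5)
  expect_equal(ci$upper, 0.5)
  set.seed(99)
  recs2 <- data.frame(dN = runif(30, 0, 0.02), dS = runif(30, 0.001, 0.03))
  a <- bootstrap_dnds_ci(recs2, n_boot = 2000, seed = 11)
  b <- bootstrap_dnds_ci(recs2, n_boot = 2000, seed = 11)
  expect_identical(a[c("point", "lower", "upper")],
                   b[c("point", "lower", "upper")])
  expect_lte(a$lower, a$point)
  expect_gte(a$upper, a$point)
})

test_that("more bootstrap samples shrink the Monte-Carlo error of the CI", {
  set.seed(7)
  recs <- data.frame(dN = runif(25, 0, 0.02), dS = runif(25, 0.001, 0.03))
  upper_small <- vapply(1:10, function(s)
    bootstrap_dnds_ci(recs, n_boot = 200, seed = s)$upper, numeric(1))
  upper_large <- vapply(1:10, function(s)
    bootstrap_dnds_ci(recs, n_boot = 4000, seed = s)$upper, numeric(1))
  expect_lt(sd(upper_large), sd(upper_small))
})

test_that("replicates with zero mean dS are redrawn and counted", {
  recs <- data.frame(dN = c(0.01, 0.02, 0.01), dS = c(0, 0, 0.03))
  ci <- bootstrap_dnds_ci(recs, n_boot = 300, seed = 5)
  expect_gt(ci$n_redrawn, 0)
  expect_true(is.finite(ci$lower) && is.finite(ci$upper))
})
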
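test_that("the same configuration and seed reproduce the trio exactly", {
  cfg <- sim_config(seed = 7, n_chromosomes = 1, chromosome_length = 60000,
                    n_genes = 10)
  a <- simulate_trio(cfg)
  b <- simulate_trio(cfg)
  expect_identical(a$calls1, b$calls1)
  expect_identical(a$calls2, b$calls2)
  expect_identical(as.character(a$reference), as.character(b$reference))
  expect_identical(a$truth$planted_variants, b$truth$planted_variants)
})

test_that("gene models have valid reading frames on both strands", {
  trio <- small_trio()
  genes <- trio$models$genes
  exons <- trio$models$exons
  expect_true(any(genes$strand == "-"))  # strand handling exercised
  for (id in genes$gene_id) {
    gex <- exons[exons$gene_id == id, ]
    gex <- gex[order(gex$rank), ]
    strand <- genes$strand[genes$gene_id == id]
    chrom <- genes$chromosome[genes$gene_id == id]
    cds <- unlist(lapply(seq_len(nrow(gex)), function(e) {
      s <- strsplit(as.character(Biostrings::subseq(
        trio$reference[[chrom]], gex$start[e], gex$end[e])), "")[[1]]
      if (strand == "-") rev(unname(.ORACLE_COMP[s])) else s
    }))
    expect_equal(length(cds) %% 3, 0)
    expect_equal(paste(cds[1:3], collapse = ""), "ATG")
    codons <- apply(matrix(cds, nrow = 3), 2, paste, collapse = "")
    expect_true(codons[length(codons)] %in% c("TAA", "TAG", "TGA"))
    ## no internal stop in the reference frame
    expect_false(any(codons[-length(codons)] %in% c("TAA", "TAG", "TGA")))
  }
})

test_that("a parent with zero mutation rate emits only hemi-SNP artifacts", {
  trio <- simulate_trio(sim_config(seed = 11, n_chromosomes = 1,
                                   chromosome_length = 80000, n_genes = 10,
                                   mutation_rate_parent1 = 0,
                                   shared_mutation_rate = 0,
                                   mutation_rate_parent2 = 0.004,
                                   hemi_snp_fraction = 0.05))
  expect_gt(nrow(trio$calls1), 0)
  expect_true(all(trio$calls1$alt_frequency > 0.2 &
                    trio$calls1$alt_frequency < 0.8))
})

test_that("planted SNP count falls in the central 99% binomial interval", {
  cfg <- sim_config(seed = 31, n_chromosomes = 2, chromosome_length = 500000,
                    n_genes = 20, mutation_rate_parent1 = 0.002,
                    mutation_rate_parent2 = 0, shared_mutation_rate = 0,
                    coding_rate_scale = 1, hemi_snp_fraction = 0)
  trio <- simulate_trio(cfg)
  n_callable <- sum(trio$callable$end - trio$callable$start + 1)
  observed <- sum(trio$truth$planted_variants$parent == "parent1")
  bounds <- qbinom(c(0.005, 0.995), n_callable, 0.002)
  expect_gte(observed, bounds[1])
  expect_lte(observed, bounds[2])
})

test_that("hemi artifacts are the only calls with non-fixed allele frequency", {
  trio <- small_trio()
  for (calls in list(trio$calls1, trio$calls2)) {
    hemi_pos <- trio$truth$hemi_positions
    hemi_here <- hemi_pos[hemi_pos$parent == calls$parent[1], ]
    flagged <- calls$alt_frequency < 1
    expect_setequal(paste(calls$chromosome[flagged], calls$position[flagged]),
                    paste(hemi_here$chromosome, hemi_here$position))
    expect_true(all(calls$alt_frequency[!flagged] == 1))
  }
})

test_that("callable masks cover close to the requested fraction", {
  trio <- small_trio()
  cfg <- trio$config
  for (ch in unique(trio$callable$chromosome)) {
    sub <- trio$callable[trio$callable$chromosome == ch, ]
    covered <- sum(sub$end - sub$start + 1) / cfg$chromosome_length
    expect_equal(covered, cfg$callable_fraction, tolerance = 0.03)
  }
})

test_that("undersized chromosomes are rejected", {
  expect_error(simulate_trio(sim_config(seed = 1, n_chromosomes = 1,
                                        chromosome_length = 5000,
                                        n_genes = 30)),
               "too short")
  expect_error(sim_config(mutation_rate_parent1 = 1.5), "probability")
  expect_error(sim_config(n_genes = 0), "positive count")
})

test_that("DH genotypes recombine at the Kosambi-implied fraction", {
  map <- data.frame(marker = c("m1", "m2"), chromosome = "A10",
                    pos_cM = c(0, 25 * log(3)))  # r = 0.25
  pop <- simulate_dh_population(10000, map, heritability = 0, seed = 3)
  rec <- mean(pop$genotypes[, 1] != pop$genotypes[, 2])
  expect_equal(rec, 0.25, tolerance = 0.02)
  expect_true(all(pop$genotypes %in% c(0L, 1L)))
})

test_that("markers at identical positions yield identical genotype columns", {
  map <- data.frame(marker = c("m1", "m2", "m3"), chromosome = "C02",
                    pos_cM = c(5, 5, 40))
  pop <- simulate_dh_population(300, map, heritability = 0, seed = 4)
  expect_identical(pop$genotypes[, 1], pop$genotypes[, 2])
})

test_that("zero heritability gives genotype-independent phenotypes", {
  map <- data.frame(marker = sprintf("m%d", 1:11), chromosome = "A10",
                    pos_cM = seq(0, 100, 10))
  qtl <- data.frame(chromosome = "A10", pos_cM = 50, effect = 2)
  below <- vapply(1:12, function(i) {
    pop <- simulate_dh_population(150, map, qtl, heritability = 0, seed = 100 + i)
    sc <- hk_scan(pop)
    th <- permutation_threshold(pop, n_perm = 200, alpha = 0.05, seed = i)
    sc$peak_lod < th$threshold
  }, logical(1))
  ## each replicate clears the alpha = 0.05 bar with probability ~0.95
  expect_gte(sum(below), 9)
})

test_that("QTL outside the map span are rejected", {
  map <- data.frame(marker = c("m1", "m2"), chromosome = "A10", pos_cM = c(0, 50))
  expect_error(simulate_dh_population(
    50, map, data.frame(chromosome = "A10", pos_cM = 70, effect = 1),
    heritability = 0.5, seed = 1), "outside the map span")
})

test_that("full heritability makes the phenotype a deterministic genotype sum", {
  map <- data.frame(marker = sprintf("m%d", 1:6), chromosome = "A03",
                    pos_cM = seq(0, 50, 10))
  qtl <- data.frame(chromosome = "A03", pos_cM = c(10, 40), effect = c(1, 2))
  pop <- simulate_dh_population(80, map, qtl, heritability = 1, seed = 9)
  ## phenotype must take values in the lattice of QTL-effect sums
  expect_true(all(pop$phenotype %in% c(0, 1, 2, 3)))
})
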
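## Sub-seeds for replicate streams, kept inside 32-bit integer range
## whatever the top-level seed.
.derive_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 1000003 + k) %% 2147483629) + 1L

## Study-level simulation experiments: the repeated-replicate runs behind
## the calibration and recovery analyses. Problem sizes follow the study
## design (225 DH lines, 1000-permutation thresholds, 20-of-500 planted
## enrichment); replicate counts are the experiment defaults documented in
## the methods vignette.

#' Type-I error of the GO permutation test on null tables
#'
#' Simulates gene-load tables with no enriched term, runs the permutation
#' test on each, and returns the fraction of all term-level p-values below
#' `alpha`.
#'
#' @param n_tables number of null tables (default 200).
#' @param n_genes,n_terms table dimensions.
#' @param n_permutations permutations per table.
#' @param alpha nominal level checked (default 0.05).
#' @param seed integer seed.
#' @return list with `fraction_significant`, `n_tests`, and the per-table
#'   fractions.
#' @export
go_type1_calibration <- function(n_tables = 200L, n_genes = 400L,
                                 n_terms = 40L, n_permutations = 999L,
                                 alpha = 0.05, seed = 1L) {
  per_table <- numeric(n_tables)
  n_tests <- 0L
  n_sig <- 0L
  for (i in seq_len(n_tables)) {
    gl <- simulate_gene_loads(n_genes = n_genes, n_terms = n_terms,
                              enriched_term_effect = 1,
                              seed = .derive_seed(seed, 100000 + i))
    res <- go_permutation_test(gl$loads, gl$annotations,
                               n_permutations = n_permutations,
                               seed = .derive_seed(seed, 200000 + i))
    per_table[i] <- mean(res$p_value < alpha)
    n_tests <- n_tests + nrow(res)
    n_sig <- n_sig + sum(res$p_value < alpha)
  }
  list(fraction_significant = n_sig / n_tests, n_tests = n_tests,
       per_table = per_table)
}

#' Detection of a planted enriched GO term across replicates
#'
#' Replicates the planted-enrichment design (a designated term whose genes
#' carry an elevated nonsynonymous rate) and reports how often the planted
#' term attains the smallest permutation p-value.
#'
#' @param n_reps number of replicates (default 100).
#' @param effect rate multiplier for the planted term's genes (default 5).
#' @param n_genes,n_terms,n_enriched_genes table design (default 20 genes
#'   of 500 carry the planted term).
#' @param n_permutations permutations per replicate.
#' @param seed integer seed.
#' @return list with `fraction_ranked_first` and the per-replicate logical
#'   vector.
#' @export
go_planted_rank_experiment <- function(n_reps = 100L, effect = 5,
                                       n_genes = 500L, n_terms = 50L,
                                       n_enriched_genes = 20L,
                                       n_permutations = 999L, seed = 1L) {
  first <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    gl <- simulate_gene_loads(n_genes = n_genes, n_terms = n_terms,
                              enriched_term_effect = effect,
                              n_enriched_genes = n_enriched_genes,
                              seed = .derive_seed(seed, 300000 + i))
    res <- go_permutation_test(gl$loads, gl$annotations,
                               n_permutations = n_permutations,
                               seed = .derive_seed(seed, 400000 + i))
    first[i] <- res$p_value[res$term_id == gl$enriched_term] == min(res$p_value)
  }
  list(fraction_ranked_first = mean(first), first = first)
}

.default_scan_map <- function(spacing_cM = 10, length_cM = 100,
                              chromosome = "A10") {
  pos <- seq(0, length_cM, spacing_cM)
  data.frame(marker = sprintf("m%02d", seq_along(pos)),
             chromosome = chromosome, pos_cM = pos,
             stringsAsFactors = FALSE)
}

#' Type-I error of the scan-plus-permutation-threshold procedure
#'
#' Simulates null DH populations (no QTL), scans each, computes its
#' permutation threshold, and reports the fraction of replicates whose
#' peak LOD clears the threshold.
#'
#' @param n_sims number of null simulations (default 200).
#' @param n_lines DH population size (default 225, the study population).
#' @param n_perm permutations per threshold.
#' @param alpha threshold level (default 0.05).
#' @param map marker map (default: one 100 cM chromosome, 10 cM spacing).
#' @param seed integer seed.
#' @return list with `fraction_significant` and the per-replicate logical
#'   vector.
#' @export
qtl_null_calibration <- function(n_sims = 200L, n_lines = 225L,
                                 n_perm = 500L, alpha = 0.05,
                                 map = .default_scan_map(), seed = 1L) {
  sig <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    pop <- simulate_dh_population(n_lines, map, qtl = NULL,
                                  heritability = 0, seed = .derive_seed(seed, 500000 + i))
    sc <- hk_scan(pop)
    th <- permutation_threshold(pop, n_perm = n_perm, alpha = alpha,
                                seed = .derive_seed(seed, 600000 + i))
    sig[i] <- sc$peak_lod > th$threshold
  }
  list(fraction_significant = mean(sig), significant = sig)
}

#' Localization error for a planted QTL
#'
#' Replicates the remapping design: one QTL of the requested effect size
#' (in phenotypic standard deviations) planted on a densely marked
#' chromosome, scanned by Haley-Knott regression; reports the absolute
#' peak-position errors.
#'
#' @param n_reps number of replicates (default 200).
#' @param n_lines DH population size (default 225).
#' @param effect_sd QTL effect as a multiple of the phenotypic SD
#'   (default 0.5).
#' @param qtl_pos_cM true QTL position (default 45).
#' @param spacing_cM marker spacing of the dense map (default 2).
#' @param seed integer seed.
#' @return list with `median_abs_error_cM` and the per-replicate errors.
#' @export
qtl_recovery_experiment <- function(n_reps = 200L, n_lines = 225L,
                                    effect_sd = 0.5, qtl_pos_cM = 45,
                                    spacing_cM = 2, seed = 1L) {
  ## effect a in SD units fixes h2 = a^2 / 4 on a unit-variance phenotype
  h2 <- effect_sd^2 / 4
  map <- .default_scan_map(spacing_cM = spacing_cM)
  qtl <- data.frame(chromosome = map$chromosome[1], pos_cM = qtl_pos_cM,
                    effect = effect_sd)
  errs <- vapply(seq_len(n_reps), function(i) {
    pop <- simulate_dh_population(n_lines, map, qtl, heritability = h2,
                                  seed = .derive_seed(seed, 700000 + i))
    abs(hk_scan(pop)$peak_position - qtl_pos_cM)
  }, numeric(1))
  list(median_abs_error_cM = median(errs), errors = errs)
}

#' Simulate per-gene (dN, dS) records with a known true ratio of means
#'
#' Substitution counts are Poisson at per-site rates chosen so the expected
#' genome-wide ratio of means equals `true_ratio`.
#'
#' @param n_genes number of genes.
#' @param true_ratio target E\[dN\] / E\[dS\].
#' @param p_s expected synonymous substitutions per synonymous site.
#' @param seed integer seed.
#' @return data frame of records usable by [aggregate_dnds()] /
#'   [bootstrap_dnds_ci()].
#' @export
simulate_dnds_records <- function(n_genes = 100L, true_ratio = 0.5,
                                  p_s = 0.002, seed = 1L) {
  set.seed(seed)
  s_sites <- runif(n_genes, 150, 250)
  n_sites <- 3 * s_sites
  p_n <- true_ratio * p_s
  ns <- rpois(n_genes, n_sites * p_n)
  ss <- rpois(n_genes, s_sites * p_s)
  data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
             n_sites = n_sites, s_sites = s_sites,
             n_subs = ns, s_subs = ss,
             dN = ns / n_sites, dS = ss / s_sites,
             stringsAsFactors = FALSE)
}

#' Coverage of the paired-bootstrap confidence interval
#'
#' Repeatedly simulates (dN, dS) records whose true ratio of means is
#' known, builds the percentile bootstrap interval on each replicate, and
#' reports how often it covers the truth.
#'
#' @param n_reps outer replicates (default 500).
#' @param n_genes genes per replicate.
#' @param n_boot bootstrap samples per interval.
#' @param true_ratio the known ratio (default 0.5).
#' @param level interval level (default 0.95).
#' @param seed integer seed.
#' @return list with `coverage` and the per-replicate logical vector.
#' @export
bootstrap_coverage_experiment <- function(n_reps = 500L, n_genes = 100L,
                                          n_boot = 1000L, true_ratio = 0.5,
                                          level = 0.95, seed = 1L) {
  covered <- vapply(seq_len(n_reps), function(i) {
    recs <- simulate_dnds_records(n_genes = n_genes, true_ratio = true_ratio,
                                  seed = .derive_seed(seed, 800000 + i))
    ci <- bootstrap_dnds_ci(recs, n_boot = n_boot, level = level,
                            seed = .derive_seed(seed, 900000 + i))
    ci$lower <= true_ratio && true_ratio <= ci$upper
  }, logical(1))
  list(coverage = mean(covered), covered = covered)
}
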
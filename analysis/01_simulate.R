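#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs -- a reference genome with
# annotated gene models, two inbred parents' reference-based call sets
# (including hemi-SNP artifacts), GO annotation, callable masks, and a
# 225-line doubled-haploid population with one planted QTL. Everything is
# written in standard interchange formats under results/sim/ so the later
# stages run from files, as the real pipeline would.

suppressPackageStartupMessages(library(parentdiff))

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 20260925, n_chromosomes = 4,
                  chromosome_length = 250000, n_genes = 40,
                  mutation_rate_parent1 = 0.0025,
                  mutation_rate_parent2 = 0.0025,
                  shared_mutation_rate = 0.002,
                  hemi_snp_fraction = 0.05)
trio <- simulate_trio(cfg)

write_reference_fasta(trio$reference, file.path(out, "reference.fasta"))
write_gene_models_gff3(trio$models, file.path(out, "genes.gff3"))
write_calls_vcf(trio$calls1, file.path(out, "parent1.vcf"))
write_calls_vcf(trio$calls2, file.path(out, "parent2.vcf"))
write_callable_bed(trio$callable, file.path(out, "callable.bed"))
write.table(trio$go, file.path(out, "go_annotations.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(trio$term_names, file.path(out, "go_term_names.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_truth_json(trio$truth, file.path(out, "truth.json"))

map <- data.frame(marker = sprintf("m%02d", 1:21), chromosome = "A10",
                  pos_cM = seq(0, 100, 5))
qtl <- data.frame(chromosome = "A10", pos_cM = 45, effect = 0.5)
pop <- simulate_dh_population(225, map, qtl, heritability = 0.0625,
                              seed = 20260925)
write_dh_population(pop, file.path(out, "dh"))

message(sprintf(
  "simulated %d + %d calls (%d planted variants, %d hemi artifacts), %d genes, 225 DH lines",
  nrow(trio$calls1), nrow(trio$calls2), nrow(trio$truth$planted_variants),
  nrow(trio$truth$hemi_positions), nrow(trio$models$genes)))
message("inputs written under ", out)
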
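#!/usr/bin/env Rscript

# Stage 2: the SNP-list construction. Filters each parent's calls on the
# four evidence criteria (Q >= 30, frequency >= 5%, depth >= 5,
# p-not-ref >= 0.90), excludes hemi-SNPs, builds the three lists (shared
# with both parents, parent-1 only, parent-2 only), and applies the
# manual-review accuracy correction to the polymorphic count.

suppressPackageStartupMessages(library(parentdiff))

sim <- "results/sim"
p1 <- read_calls_vcf(file.path(sim, "parent1.vcf"), parent = "parent1")
p2 <- read_calls_vcf(file.path(sim, "parent2.vcf"), parent = "parent2")

f1 <- flag_hemi_snps(filter_calls(p1))
f2 <- flag_hemi_snps(filter_calls(p2))
cmp <- compare_parents(f1$clean, f2$clean)
print(cmp)

write_calls_vcf(cmp$shared_vs_reference, file.path(sim, "shared.vcf"))
write_calls_vcf(cmp$parent1_only, file.path(sim, "parent1_only.vcf"))
write_calls_vcf(cmp$parent2_only, file.path(sim, "parent2_only.vcf"))
write_calls_vcf(cmp$polymorphic_between_parents,
                file.path(sim, "polymorphic.vcf"))

## accuracy correction with the study's manual-review design (500 reviewed)
acc <- estimate_accuracy(500, 414)
print(acc)
summary <- data.frame(
  list = c("shared_vs_reference", "parent1_only", "parent2_only",
           "polymorphic", "hemi_excluded_p1", "hemi_excluded_p2"),
  n_calls = c(nrow(cmp$shared_vs_reference), nrow(cmp$parent1_only),
              nrow(cmp$parent2_only), nrow(cmp$polymorphic_between_parents),
              nrow(f1$hemi), nrow(f2$hemi)))
summary$corrected <- round(acc$corrected_count(summary$n_calls))
write.table(summary, "results/comparison_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("three-list summary written to results/comparison_summary.tsv")
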
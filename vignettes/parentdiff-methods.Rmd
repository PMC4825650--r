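---
title: "Methods: comparing two inbred parent genomes against a reference"
author: "parentdiff"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing two inbred parent genomes against a reference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis

`parentdiff` implements the downstream half of a parent-line resequencing
comparison in an allopolyploid crop such as *Brassica napus*: two inbred
cultivars are sequenced, aligned to a common reference, and their
variant-call tables are compared to describe the molecular variation
differentiating them at the scale of the genome, the QTL interval, and the
gene. Short-read alignment and variant calling themselves are out of scope;
the pipeline starts from per-parent call tables carrying the caller's
evidence (Phred quality, depth, allele frequency, and the probability that
the base differs from the reference) and from standard annotation inputs
(FASTA reference, GFF3 gene models, GO tables, BED callable masks).

Because no processed data accompany the original study, the package ships a
first-class synthetic-data generator. It builds a reference genome with
valid gene models, plants substitutions in each parent at controlled rates,
fabricates the hemi-SNP artifacts characteristic of allopolyploid
alignments, and records everything planted in a truth object. Every
downstream stage is therefore testable against known ground truth.

# SNP filtering and the three-list comparison

Calls are kept when all four evidence criteria hold simultaneously:
quality call score >= 30 (Phred), SNP frequency >= 5%, depth >= 5, and
probability-not-reference >= 0.90. All four thresholds are inclusive, and
the probability scale is a proportion (a caller reporting percent should be
divided by 100 on import).

Because both parents are called against the same reference, comparing the
two filtered call sets yields three lists: variants shared by both parents
(same alternate allele at the same site), and variants private to each
parent. Private variants are polymorphic between the parents; that union is
the substrate for effect classification and candidate screening. Variant
identity is keyed by (chromosome, position, alternate allele), so a site
where the parents carry different alternate alleles contributes two
polymorphic records. A single genome-wide accuracy multiplier, estimated
from a manual review of a random subset of calls (for example 414 of 500
confirmed, i.e. 82.8%), corrects raw counts.

## Hemi-SNPs

In an amphidiploid, reads from a homeologous locus can map to the wrong
subgenome and produce an apparently heterozygous call in a fully inbred
line. These hemi-SNPs are excluded before any comparison. The operational
definition here is an allele frequency strictly inside a heterozygous band,
(0.2, 0.8) by default; the band is configurable because the boundary is a
judgment call, not a published constant. The generator emits artifacts with
frequencies uniform on [0.25, 0.75] from a duplicated donor segment, so the
default band separates artifacts from fixed variants perfectly in synthetic
data; on real data the separation is only as good as the caller's frequency
estimates.

# Effect classification and density

A SNP is noncoding if it overlaps no gene model's CDS. Coding SNPs are
placed in their codon (minus-strand calls are complemented first) and
translated with the standard genetic code; amino-acid identity means
synonymous. A SNP inside two overlapping models is classified per model and
counted once for density, with nonsynonymous taking precedence — overlap is
rare and the choice is conservative for enrichment purposes.

SNP density is SNPs per callable base, reported as a percentage, where
callable length is the sequence covered deeply enough (>= 5x in the study
design) for a variant to have been callable at all. Per-chromosome
densities feed a Welch two-sample t-test between the A and C subgenomes
(unpaired: the study does not describe pairing homeologous chromosomes),
and the two parents' total counts against the reference feed a
one-degree-of-freedom equal-divergence chi-square whose expectation is the
mean of the two counts.

# dN/dS

The study estimated pairwise dN/dS with CODEML after substituting each
parent's SNPs into the reference gene models. This package instead uses
Nei–Gojobori (1986) counting: expected synonymous and nonsynonymous site
counts per codon (averaged over the two sequences), substitutions counted
per changed codon with all minimal mutational pathways averaged for
multi-hit codons. At the divergences involved here (well under 1%), ML and
counting estimates converge, and counting keeps the package self-contained;
the counting core is validated against an independent pathway-enumeration
oracle in the tests. Details fixed by this implementation: the terminal
stop codon is excluded from all counts; changes creating a stop count as
nonsynonymous; pathways through an intermediate stop are discarded when an
alternative exists; a variant that itself creates a premature stop flags
the gene's record and drops that codon. A Jukes–Cantor correction is
available behind a flag but off by default — at these divergences it moves
the third decimal.

The genome-wide aggregate is the ratio of means, mean(dN)/mean(dS), not the
mean of per-gene ratios: at realistic densities most genes have dS = 0 and
no defined ratio, while the ratio of means is always defined when any
synonymous variation exists. The 95% confidence interval resamples
gene-level (dN, dS) pairs jointly (a paired bootstrap, 10,000 samples by
default) and takes percentile quantiles; replicates with resampled mean
dS = 0 are redrawn and counted. Keeping the pair intact preserves the
within-gene association between the two rates, which is the point of the
paired scheme.

One caveat the simulation makes visible: with a transition/transversion
ratio of 2 and no selection, unweighted Nei–Gojobori counting sits below 1
because transitions are disproportionately synonymous. The aggregate from
neutrally planted substitutions is therefore expected below unity; the
package's calibration experiments use direct (dN, dS) record simulation
with a known true ratio instead, where coverage of the bootstrap interval
is checked (~95%).

# GO enrichment by permutation

For each GO term the statistic is the total density of nonsynonymous SNPs
per codon over all genes annotated with the term. Significance comes from
permutation: the per-gene (nonsynonymous count, codon count) pairs are
shuffled across gene identities while the gene-to-term annotation stays
fixed, and the p-value is the fraction of permutations whose term density
is greater than or equal to the observed one, with the add-one estimator
(r+1)/(n+1) so finite permutations never report zero. 1000 permutations is
the method default.

Whether the two quantities should be shuffled as a pair or independently is
genuinely ambiguous in the source description; pairing is the default here
because it preserves the gene-length/count association that makes the
density statistic meaningful (long genes carry more SNPs), and independent
shuffling is available via `paired = FALSE` for sensitivity analysis. No
multiple-testing correction is applied to the selection at raw P < 0.01,
matching the study's reporting; a Benjamini–Hochberg q-value column is
emitted alongside. Because counts are integers, permuted and observed
densities with equal sums compare exactly — the all-genes term gets p = 1
structurally, which doubles as a conservation check.

# Read multi-mapping

`count_hits()` reports, for each read, the number of distinct genomic start
positions on either strand where the read aligns within an edit budget.
For 100 bp reads the default budget of 5 substitutions coincides with a 95%
identity threshold; Hamming distance (substitutions only) is the default
and a gapped Levenshtein mode is available. A read sampled from the genome
always counts its origin, so the minimum is 1; counts are capped at 500 and
capped reads are flagged. This is a desk-scale reimplementation for toy
genomes (<= 10 Mbp) intended to reproduce the shape of the hit-count
distribution — a heavy right skew with median 1 — not a production aligner.

# DH simulation and Haley–Knott QTL scanning

Doubled-haploid genotypes are fully homozygous and coded 0/1. The generator
walks each chromosome as a Markov chain whose adjacent-marker recombination
fractions come from the inverse Kosambi function of the map distance,
d = 25 ln((1+2r)/(1−2r)) cM; QTL positions are simulated as pseudo-markers
so their genotypes are exact, and the phenotype is the sum of additive QTL
effects plus Gaussian noise scaled so the planted narrow-sense heritability
holds exactly in expectation (a 0/1 DH locus with effect a contributes
a²/4 of variance).

The scan follows Haley–Knott regression: at 1 cM grid steps the phenotype
is regressed on the conditional expectation of the genotype given the
nearest typed flanking markers (for DH lines this conditional is an exact
two-path enumeration; at a typed marker it is the genotype itself; missing
genotypes fall back to the nearest typed markers), and
LOD = (n/2) log10(RSS0/RSS1). Grid points with a monomorphic expected
genotype are assigned LOD 0 rather than erroring. Genome-wide significance
uses the standard permutation scheme — phenotypes shuffled against genotype
rows, 1000 permutations by default, threshold at the (1−α) quantile of the
per-permutation maximum LOD. The support interval is the 1.5-LOD drop
evaluated on the scan grid (nearest grid point crossing), matching common
interval-mapping practice. Stepwise multi-QTL model selection and map
construction are out of scope; a utility re-estimates adjacent-marker
Kosambi distances from genotypes for map sanity checks, and
`recombination_rate()` reports physical/genetic span in kbp/cM.

# Candidate screening

Genes overlapping a QTL interval (partial overlap counts as inside, the
inclusive convention of reference-interval practice) are screened for
nonsynonymous variation; candidates are the subset annotated with GO terms
whose names match a configurable keyword map — flowering:
flower/floral/vernalization, root: root, by default, since the study states
the rule but not a term list. Each interval reports only the categories
relevant to its traits. The focal insertion polymorphism enters not as a
called variant (indel calling is out of scope) but as a scored marker; its
association with ecotype is a two-sided Fisher exact test on the 2×2
presence-by-ecotype table.

# The synthetic generator: what it does and does not emulate

The generator reproduces the study design downstream of alignment: two
inbred call sets diverged from one reference at ~0.2–0.6% per-parent rates,
reduced divergence inside CDS (`coding_rate_scale`, default 0.6), a
transition bias of 2, ~82% callable sequence (the study's 532/645 Mb),
hemi-SNP artifacts at 5% of calls, a 5,624 bp insertion planted in the
first exon of a focal flowering gene, GO tables with an optionally enriched
term, and DH populations of 225 lines. Chromosome names alternate A/C so
subgenome comparisons are exercised. Two fields extend the obvious knobs: a
`shared_mutation_rate` (variants planted in both parents) so the shared
list of the three-way comparison is non-empty, and a
`reverse_strand_fraction` so minus-strand codon arithmetic is always
exercised.

It does not emulate: read-level error (calls are emitted, not reads),
linked variation or realistic linkage disequilibrium between planted SNPs,
indel calls, isoforms (one transcript per gene, which matches the
single-model progenitor annotations), overlapping genes, or callable-mask
fragmentation finer than 1/50 of a chromosome. Passing tests therefore
demonstrate correctness of the downstream machinery on clean inputs, not
robustness to caller pathologies.

# Numerical choices and problem sizes

Internal coordinates are 1-based inclusive throughout — the Bioconductor
convention — with format shifts handled at the I/O boundary (GFF3 written
1-based, BED via rtracklayer's 0-based conversion). Seeds are explicit
arguments everywhere randomness exists, and replicate streams derive
sub-seeds modulo 2³¹ so any 32-bit seed is safe. Permutation p-values use
(r+1)/(n+1); bootstrap intervals use percentile quantiles.

The calibration experiments run at the sizes stated in their defaults: 200
null gene-load tables (400 genes × 40 terms, 999 permutations) for the GO
type-I error; 100 replicates of the 20-of-500 five-fold planted term; 200
null DH populations of 225 lines (500-permutation thresholds) for the
scan-plus-threshold type-I error; 200 replicates for QTL localization
(0.5 SD effect, 2 cM marker spacing); and 500 outer replicates (100 genes,
1000 bootstrap samples) for interval coverage. These sizes put Monte-Carlo
error comfortably inside the tolerances being checked while keeping the
full suite to a few minutes on one core.

# Known limitations

The counting dN/dS estimator ignores transition bias in its site
definitions (see above); codon-model ML would be the upgrade path. The
equal-divergence test treats calls as independent, ignoring linkage. The
multimap profiler is quadratic and unsuitable beyond toy genomes. The
candidate screen's keyword matching is a stand-in for a curated GO slim.
The HK scan fits a single-QTL model only; closely linked QTL will merge
into one peak.
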
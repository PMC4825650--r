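Package: parentdiff
Title: Parent-Line Resequencing Comparison and QTL Rescanning for Allopolyploid Brassica
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-based comparison of two inbred parent genomes from
    variant-call tables: four-criterion SNP filtering, hemi-SNP exclusion for
    allopolyploids, three-list parent-versus-parent comparison, coding-effect
    classification against gene models, SNP density over callable sequence,
    Nei-Gojobori dN/dS with a paired bootstrap confidence interval on the
    genome-wide ratio of means, GO-term nonsynonymous-enrichment permutation
    testing, read multi-mapping profiling on toy genomes, candidate-gene
    screening within QTL intervals, and Haley-Knott regression QTL scanning
    for doubled-haploid populations on a Kosambi map with permutation
    thresholds. Includes a synthetic-data generator that plants variants,
    hemi-SNP artifacts, an enriched GO term, and QTL with known truth so the
    whole pipeline is testable without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    vcfR,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
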
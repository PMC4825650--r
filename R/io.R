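## Readers and writers for the interchange formats the pipeline speaks:
## FASTA (Biostrings), GFF3 and BED (rtracklayer), VCF v4.2 (vcfR for
## reading; a small emitter for writing uncompressed text), TSV/CSV/JSON.

#' Write / read the reference sequences as FASTA
#' @param reference named [Biostrings::DNAStringSet].
#' @param path file path.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(reference, path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write / read gene models as GFF3
#'
#' Each gene is one `gene` feature plus one `CDS` feature per exon
#' (Parent = gene ID); coordinates are 1-based inclusive per the GFF3
#' standard, phase is derived from the cumulative CDS length in transcript
#' order.
#'
#' @param models gene models list (`genes`, `exons`).
#' @param path file path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  genes <- models$genes
  exons <- models$exons
  gr_gene <- GenomicRanges::GRanges(
    seqnames = genes$chromosome,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand,
    type = "gene", ID = genes$gene_id)
  phase <- integer(nrow(exons))
  for (id in unique(exons$gene_id)) {
    sel <- which(exons$gene_id == id)
    sel <- sel[order(exons$rank[sel])]
    w <- exons$end[sel] - exons$start[sel] + 1L
    phase[sel] <- c(0L, cumsum(w)[-length(w)] %% 3L)
  }
  gr_cds <- GenomicRanges::GRanges(
    seqnames = exons$chromosome,
    ranges = IRanges::IRanges(exons$start, exons$end),
    strand = exons$strand,
    type = "CDS", Parent = exons$gene_id, phase = phase)
  gr <- c(gr_gene, gr_cds)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_gene_models_gff3
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- as.data.frame(gr)
  is_gene <- md$type == "gene"
  genes <- data.frame(gene_id = as.character(md$ID[is_gene]),
                      chromosome = as.character(md$seqnames[is_gene]),
                      strand = as.character(md$strand[is_gene]),
                      start = md$start[is_gene], end = md$end[is_gene],
                      stringsAsFactors = FALSE)
  is_cds <- md$type == "CDS"
  parent <- vapply(md$Parent[is_cds], function(p) as.character(p)[1L],
                   character(1))
  exons <- data.frame(gene_id = parent,
                      chromosome = as.character(md$seqnames[is_cds]),
                      strand = as.character(md$strand[is_cds]),
                      start = md$start[is_cds], end = md$end[is_cds],
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(split(exons, exons$gene_id), function(d) {
    d <- d[order(d$start, decreasing = (d$strand[1L] == "-")), , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(exons) <- NULL
  genes$codon_count <- vapply(genes$gene_id, function(id)
    sum(exons$end[exons$gene_id == id] - exons$start[exons$gene_id == id] + 1L) %/% 3L,
    integer(1))
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$rank), ,
                 drop = FALSE]
  rownames(exons) <- rownames(genes) <- NULL
  list(genes = genes, exons = exons)
}

#' Write / read a per-parent call table as VCF v4.2
#'
#' Writes an uncompressed single-sample VCF carrying the evidence fields in
#' INFO (`DP` depth, `AF` alternate frequency, `PNR` probability the base
#' is not the reference) and the Phred quality in QUAL. Reading goes
#' through `vcfR`.
#'
#' @param calls call table (see [filter_calls()]).
#' @param path file path.
#' @param parent parent label stored on read (reader argument).
#' @export
write_calls_vcf <- function(calls, path) {
  .validate_calls(calls)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=parentdiff",
    '##INFO=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
    '##INFO=<ID=AF,Number=1,Type=Float,Description="Alternate allele frequency">',
    '##INFO=<ID=PNR,Number=1,Type=Float,Description="Probability base differs from reference">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(calls)) {
    info <- sprintf("DP=%d;AF=%s;PNR=%s", as.integer(calls$depth),
                    format(calls$alt_frequency, trim = TRUE, scientific = FALSE),
                    format(calls$prob_not_ref, trim = TRUE, scientific = FALSE))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\t.\t%s",
                       calls$chromosome, calls$position, calls$ref_allele,
                       calls$alt_allele,
                       format(calls$quality, trim = TRUE, scientific = FALSE),
                       info), con)
  }
  invisible(path)
}

#' @rdname write_calls_vcf
#' @export
read_calls_vcf <- function(path, parent = NA_character_) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  data.frame(chromosome = fix[, "CHROM"],
             position = as.integer(fix[, "POS"]),
             ref_allele = fix[, "REF"],
             alt_allele = fix[, "ALT"],
             quality = as.numeric(fix[, "QUAL"]),
             depth = as.integer(vcfR::extract.info(v, "DP", as.numeric = TRUE)),
             alt_frequency = vcfR::extract.info(v, "AF", as.numeric = TRUE),
             prob_not_ref = vcfR::extract.info(v, "PNR", as.numeric = TRUE),
             parent = parent,
             stringsAsFactors = FALSE)
}

#' Write / read callable-interval masks as BED
#'
#' Coordinates are 1-based inclusive in memory; rtracklayer performs the
#' BED 0-based half-open conversion.
#'
#' @param callable data frame (`chromosome`, `start`, `end`).
#' @param path file path.
#' @export
write_callable_bed <- function(callable, path) {
  gr <- GenomicRanges::GRanges(callable$chromosome,
                               IRanges::IRanges(callable$start, callable$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname write_callable_bed
#' @export
read_callable_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chromosome = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr), stringsAsFactors = FALSE)
}

#' Write / read per-gene load tables (TSV with pipe-separated GO terms)
#'
#' @param loads data frame (`gene_id`, `ns_snp_count`, `codon_count`).
#' @param annotations data frame (`gene_id`, `term_id`).
#' @param path file path.
#' @export
write_gene_loads_tsv <- function(loads, annotations, path) {
  terms <- vapply(loads$gene_id, function(id)
    paste(sort(annotations$term_id[annotations$gene_id == id]), collapse = "|"),
    character(1))
  out <- data.frame(gene_id = loads$gene_id,
                    ns_snp_count = loads$ns_snp_count,
                    codon_count = loads$codon_count,
                    go_terms = terms, stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_loads_tsv
#' @export
read_gene_loads_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  ann <- do.call(rbind, lapply(seq_len(nrow(d)), function(i) {
    t <- strsplit(d$go_terms[i], "|", fixed = TRUE)[[1]]
    t <- t[nzchar(t)]
    if (length(t) == 0L) return(NULL)
    data.frame(gene_id = d$gene_id[i], term_id = t, stringsAsFactors = FALSE)
  }))
  list(loads = d[, c("gene_id", "ns_snp_count", "codon_count")],
       annotations = ann)
}

#' Write / read a DH population as three CSV files
#'
#' Writes `<prefix>_genotypes.csv` (lines x markers, 0/1, NA blank),
#' `<prefix>_map.csv` (marker, chromosome, pos_cM) and
#' `<prefix>_phenotype.csv`.
#'
#' @param pop `"dh_population"` object.
#' @param prefix path prefix.
#' @export
write_dh_population <- function(pop, prefix) {
  write.csv(as.data.frame(pop$genotypes),
            paste0(prefix, "_genotypes.csv"), row.names = FALSE)
  write.csv(pop$map, paste0(prefix, "_map.csv"), row.names = FALSE)
  write.csv(data.frame(phenotype = pop$phenotype),
            paste0(prefix, "_phenotype.csv"), row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_dh_population
#' @export
read_dh_population <- function(prefix) {
  G <- as.matrix(read.csv(paste0(prefix, "_genotypes.csv"),
                          check.names = FALSE))
  storage.mode(G) <- "integer"
  out <- list(map = read.csv(paste0(prefix, "_map.csv"),
                             stringsAsFactors = FALSE),
              genotypes = G,
              phenotype = read.csv(paste0(prefix, "_phenotype.csv"))$phenotype,
              qtl = NULL)
  class(out) <- "dh_population"
  out
}

#' Write the synthetic truth object as JSON
#' @param truth truth list from [simulate_trio()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
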
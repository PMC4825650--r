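#' Number of genomic loci a read maps to within an edit-distance budget
#'
#' Counts the distinct genomic start positions, on either strand, at which
#' the read aligns with at most `max_edit` mismatches. The default is
#' Hamming mode (substitutions only): for 100 bp reads an edit budget of 5
#' coincides with a 95% sequence-identity threshold. A gapped mode
#' (`mode = "edit"`, Levenshtein distance) is available. Counts are capped
#' at `max_report`. Intended for toy and synthetic genomes, not as a
#' production aligner.
#'
#' @param read character or [Biostrings::DNAString] read sequence.
#' @param genome named [Biostrings::DNAStringSet] (or character vector).
#' @param max_edit maximum edit distance (default 5).
#' @param max_report cap on the reported number of hits (default 500).
#' @param mode `"hamming"` (substitutions only, default) or `"edit"`
#'   (with indels).
#' @return integer hit count (capped).
#' @export
count_hits <- function(read, genome, max_edit = 5L, max_report = 500L,
                       mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L)
    stop("empty genome")
  read <- Biostrings::DNAString(as.character(read))
  if (length(read) < 1L) stop("read length must be >= 1")
  stopifnot(max_edit >= 0L, max_report >= 1L)
  with_indels <- mode == "edit"
  rc <- Biostrings::reverseComplement(read)
  total <- 0L
  for (i in seq_along(genome)) {
    fwd <- Biostrings::matchPattern(read, genome[[i]], max.mismatch = max_edit,
                                    with.indels = with_indels)
    rev <- Biostrings::matchPattern(rc, genome[[i]], max.mismatch = max_edit,
                                    with.indels = with_indels)
    total <- total + length(unique(c(Biostrings::start(fwd),
                                     Biostrings::start(rev))))
    if (total >= max_report) return(as.integer(max_report))
  }
  as.integer(total)
}

#' Multi-mapping profile of a read set
#'
#' Applies [count_hits()] to every read and summarizes the per-read hit
#' counts: the full array, its histogram, and the median. Reads at the
#' reporting cap are flagged.
#'
#' @param reads character vector or [Biostrings::DNAStringSet] of reads
#'   (>= 1 read).
#' @inheritParams count_hits
#' @return list of class `"hit_profile"`: `per_read_hits`, `histogram`
#'   (data frame of hit count and frequency), `median_hits`, `max_reported`,
#'   `n_capped`.
#' @export
multimap_profile <- function(reads, genome, max_edit = 5L, max_report = 500L,
                             mode = c("hamming", "edit")) {
  mode <- match.arg(mode)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  if (length(reads) < 1L) stop("need at least one read")
  hits <- vapply(seq_along(reads), function(i)
    count_hits(reads[[i]], genome, max_edit, max_report, mode), integer(1))
  tab <- table(hits)
  out <- list(per_read_hits = hits,
              histogram = data.frame(hits = as.integer(names(tab)),
                                     frequency = as.integer(tab)),
              median_hits = median(hits),
              max_reported = as.integer(max_report),
              n_capped = sum(hits >= max_report))
  class(out) <- "hit_profile"
  out
}

#' @exportS3Method base::print
print.hit_profile <- function(x, ...) {
  cat(sprintf("Multi-mapping profile of %d reads: median %s hit(s), max %d%s\n",
              length(x$per_read_hits), format(x$median_hits),
              max(x$per_read_hits),
              if (x$n_capped > 0)
                sprintf(" (%d read(s) at the %d-hit cap)", x$n_capped,
                        x$max_reported) else ""))
  invisible(x)
}
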
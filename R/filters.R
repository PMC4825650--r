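#' Filter reference-based SNP calls on the four evidence criteria
#'
#' Keeps exactly the calls meeting all four thresholds simultaneously:
#' Phred quality, alternate-allele frequency, read depth, and the
#' probability that the base differs from the reference ("p not ref").
#' All thresholds are inclusive (`>=`).
#'
#' @param calls data frame of calls with columns `chromosome`, `position`,
#'   `ref_allele`, `alt_allele`, `quality`, `depth`, `alt_frequency`,
#'   `prob_not_ref` (and optionally `parent`).
#' @param min_quality minimum Phred quality call score (default 30).
#' @param min_frequency minimum SNP frequency as a proportion (default 0.05).
#' @param min_depth minimum read depth (default 5).
#' @param min_prob_not_ref minimum probability the base differs from the
#'   reference, as a proportion (default 0.90).
#' @return The subset of `calls` passing all criteria.
#' @export
filter_calls <- function(calls, min_quality = 30, min_frequency = 0.05,
                         min_depth = 5, min_prob_not_ref = 0.90) {
  .validate_calls(calls)
  stopifnot(min_quality >= 0, min_frequency >= 0, min_frequency <= 1,
            min_depth >= 0, min_prob_not_ref >= 0, min_prob_not_ref <= 1)
  keep <- calls$quality >= min_quality &
    calls$alt_frequency >= min_frequency &
    calls$depth >= min_depth &
    calls$prob_not_ref >= min_prob_not_ref
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.CALL_COLUMNS <- c("chromosome", "position", "ref_allele", "alt_allele",
                   "quality", "depth", "alt_frequency", "prob_not_ref")

.validate_calls <- function(calls, require_evidence = TRUE) {
  if (!is.data.frame(calls)) stop("'calls' must be a data frame")
  need <- if (require_evidence) .CALL_COLUMNS else .CALL_COLUMNS[1:4]
  missing_cols <- setdiff(need, names(calls))
  if (length(missing_cols))
    stop("call table missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(calls) == 0L) return(invisible(TRUE))
  for (col in intersect(need, c("quality", "depth", "alt_frequency",
                                "prob_not_ref", "position"))) {
    bad <- which(is.na(calls[[col]]))
    if (length(bad))
      stop(sprintf("call record %d has missing '%s'", bad[1L], col))
  }
  if (any(calls$alt_frequency < 0 | calls$alt_frequency > 1))
    stop("alt_frequency must lie in [0, 1]")
  if (any(calls$depth < 0)) stop("depth must be >= 0")
  same <- which(calls$ref_allele == calls$alt_allele)
  if (length(same))
    stop(sprintf("call record %d has ref_allele == alt_allele", same[1L]))
  invisible(TRUE)
}

#' Partition calls into clean calls and hemi-SNP artifacts
#'
#' In an inbred line a genuine variant is fixed, so its alternate-allele
#' frequency sits near 0 or 1. Calls whose frequency falls strictly inside
#' the heterozygous band are flagged as hemi-SNPs -- apparent heterozygotes
#' produced by reads from a homeologous locus mapping to the wrong
#' subgenome -- and removed from the clean set. The partition is exhaustive.
#'
#' @param calls data frame of calls (see [filter_calls()]).
#' @param het_band numeric length-2 vector `(low, high)`; calls with
#'   `low < alt_frequency < high` are flagged. Default `c(0.2, 0.8)`.
#' @return list with elements `clean` and `hemi`.
#' @export
flag_hemi_snps <- function(calls, het_band = c(0.2, 0.8)) {
  .validate_calls(calls)
  stopifnot(length(het_band) == 2L, het_band[1] >= 0, het_band[2] <= 1,
            het_band[1] < het_band[2])
  is_hemi <- calls$alt_frequency > het_band[1] & calls$alt_frequency < het_band[2]
  clean <- calls[!is_hemi, , drop = FALSE]
  hemi <- calls[is_hemi, , drop = FALSE]
  rownames(clean) <- rownames(hemi) <- NULL
  list(clean = clean, hemi = hemi)
}

.call_key <- function(calls)
  paste(calls$chromosome, calls$position, calls$alt_allele, sep = "\r")

#' Three-list comparison of two parents' reference-based call sets
#'
#' Because SNPs are called relative to a common reference, comparing the two
#' per-parent call sets yields three lists: SNPs shared by both parents
#' (same alternate allele at the same site), and SNPs present in only one
#' parent. Calls present in one parent and not the other are deemed
#' polymorphic between the parents. Identity is keyed by
#' (chromosome, position, alt allele), so two parents carrying different
#' alternate alleles at one site contribute two polymorphic records.
#'
#' @param parent1,parent2 filtered, hemi-cleaned call tables.
#' @return list of class `"parent_comparison"` with elements
#'   `shared_vs_reference`, `parent1_only`, `parent2_only`, and
#'   `polymorphic_between_parents` (the union of the two parent-only lists).
#' @export
compare_parents <- function(parent1, parent2) {
  .validate_calls(parent1, require_evidence = FALSE)
  .validate_calls(parent2, require_evidence = FALSE)
  ## reference consistency at co-located sites
  site1 <- paste(parent1$chromosome, parent1$position, sep = "\r")
  site2 <- paste(parent2$chromosome, parent2$position, sep = "\r")
  m <- match(site1, site2)
  hit <- which(!is.na(m))
  bad <- hit[parent1$ref_allele[hit] != parent2$ref_allele[m[hit]]]
  if (length(bad))
    stop(sprintf("reference allele disagrees between parents at %s:%s",
                 parent1$chromosome[bad[1L]], parent1$position[bad[1L]]))
  k1 <- .call_key(parent1)
  k2 <- .call_key(parent2)
  shared <- parent1[k1 %in% k2, , drop = FALSE]
  p1_only <- parent1[!(k1 %in% k2), , drop = FALSE]
  p2_only <- parent2[!(k2 %in% k1), , drop = FALSE]
  common <- intersect(names(p1_only), names(p2_only))
  poly <- rbind(p1_only[, common, drop = FALSE], p2_only[, common, drop = FALSE])
  ord <- order(poly$chromosome, poly$position, poly$alt_allele)
  poly <- poly[ord, , drop = FALSE]
  rownames(shared) <- rownames(p1_only) <- rownames(p2_only) <- rownames(poly) <- NULL
  out <- list(shared_vs_reference = shared,
              parent1_only = p1_only,
              parent2_only = p2_only,
              polymorphic_between_parents = poly)
  class(out) <- "parent_comparison"
  out
}

#' @exportS3Method base::print
print.parent_comparison <- function(x, ...) {
  cat("Parent-vs-parent SNP comparison\n")
  cat(sprintf("  shared with both parents : %d\n", nrow(x$shared_vs_reference)))
  cat(sprintf("  parent 1 only            : %d\n", nrow(x$parent1_only)))
  cat(sprintf("  parent 2 only            : %d\n", nrow(x$parent2_only)))
  cat(sprintf("  polymorphic between parents: %d\n",
              nrow(x$polymorphic_between_parents)))
  invisible(x)
}

#' Estimate SNP-caller accuracy from manual review counts
#'
#' A random subset of automated calls is manually reviewed in an alignment
#' viewer; the confirmed fraction estimates the caller's accuracy and is
#' applied as a single genome-wide multiplier to correct raw SNP counts.
#'
#' @param n_reviewed number of calls manually reviewed (> 0).
#' @param n_confirmed number confirmed accurate (0 <= n_confirmed <= n_reviewed).
#' @return list of class `"accuracy_estimate"` with fields `n_reviewed`,
#'   `n_confirmed`, `accuracy` (proportion), `percent` (rounded to one
#'   decimal for display), and `corrected_count` (function mapping a raw
#'   count to an accuracy-corrected count).
#' @examples
#' est <- estimate_accuracy(500, 414)
#' est$percent            # 82.8
#' est$corrected_count(1e6)
#' @export
estimate_accuracy <- function(n_reviewed, n_confirmed) {
  if (n_reviewed <= 0) stop("'n_reviewed' must be > 0")
  if (n_confirmed < 0 || n_confirmed > n_reviewed)
    stop("'n_confirmed' must lie in [0, n_reviewed]")
  accuracy <- n_confirmed / n_reviewed
  out <- list(n_reviewed = n_reviewed, n_confirmed = n_confirmed,
              accuracy = accuracy,
              percent = round(100 * accuracy, 1),
              corrected_count = function(raw) raw * accuracy)
  class(out) <- "accuracy_estimate"
  out
}

#' @exportS3Method base::print
print.accuracy_estimate <- function(x, ...) {
  cat(sprintf("SNP caller accuracy: %d of %d confirmed (%.1f%%)\n",
              x$n_confirmed, x$n_reviewed, x$percent))
  invisible(x)
}
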
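.DEFAULT_KEYWORDS <- list(flowering = c("flower", "floral", "vernalization"),
                          root = c("root"))

.genes_in_category <- function(annotations, term_names, keywords) {
  nm <- tolower(term_names$name)
  hit <- rep(FALSE, nrow(term_names))
  for (k in keywords) hit <- hit | grepl(k, nm, fixed = TRUE)
  terms <- term_names$term_id[hit]
  unique(annotations$gene_id[annotations$term_id %in% terms])
}

#' Screen a QTL interval for candidate genes
#'
#' Counts the genes overlapping the interval (genes partially overlapping
#' are counted as inside), the subset carrying at least one nonsynonymous
#' SNP in their CDS, and -- for each trait category named by the interval --
#' the genes annotated with any GO term whose name matches the category's
#' keywords, split into annotated versus annotated-and-carrying. Categories
#' not among the interval's traits are reported as NA.
#'
#' @param interval list or one-row data frame with `qtl_id`, `chromosome`,
#'   `start`, `end`, and `traits` (character vector, or comma-separated
#'   string, drawn from the names of `keywords`).
#' @param models gene models (see [classify_effects()]).
#' @param classified classified call table ([classify_effects()] output) for
#'   the polymorphic-between-parents set.
#' @param annotations gene_id/term_id table.
#' @param term_names term_id/name table.
#' @param keywords named list of keyword vectors; a GO term belongs to a
#'   category when its (lower-cased) name contains any keyword. Default:
#'   flowering = flower/floral/vernalization, root = root.
#' @return list with `summary` (one-row data frame: `qtl_id`, `chromosome`,
#'   `traits`, `total_genes`, `genes_with_ns`, and per category
#'   `<cat>_annotated` / `<cat>_with_ns`) and `genes` (per-category id
#'   lists plus `with_ns`).
#' @export
screen_interval <- function(interval, models, classified, annotations,
                            term_names, keywords = .DEFAULT_KEYWORDS) {
  if (is.data.frame(interval)) interval <- as.list(interval[1L, ])
  stopifnot(all(c("qtl_id", "chromosome", "start", "end", "traits") %in%
                  names(interval)))
  if (interval$start >= interval$end) stop("interval start must be < end")
  traits <- interval$traits
  if (length(traits) == 1L && grepl(",", traits))
    traits <- trimws(strsplit(traits, ",")[[1]])
  traits <- unlist(traits)
  genes <- models$genes
  inside <- genes$chromosome == interval$chromosome &
    genes$start <= interval$end & genes$end >= interval$start
  ids <- genes$gene_id[inside]
  if (length(ids) == 0L)
    warning(sprintf("interval %s contains no genes", interval$qtl_id))
  ns_genes <- unique(classified$gene_id[
    !is.na(classified$gene_id) & classified$effect == "nonsynonymous"])
  carrying <- intersect(ids, ns_genes)
  row <- data.frame(qtl_id = interval$qtl_id,
                    chromosome = interval$chromosome,
                    traits = paste(traits, collapse = ","),
                    total_genes = length(ids),
                    genes_with_ns = length(carrying),
                    stringsAsFactors = FALSE)
  gene_lists <- list(with_ns = carrying)
  for (cat in names(keywords)) {
    if (cat %in% traits) {
      cat_genes <- intersect(ids, .genes_in_category(annotations, term_names,
                                                     keywords[[cat]]))
      row[[paste0(cat, "_annotated")]] <- length(cat_genes)
      row[[paste0(cat, "_with_ns")]] <- length(intersect(cat_genes, carrying))
      gene_lists[[cat]] <- cat_genes
    } else {
      row[[paste0(cat, "_annotated")]] <- NA_integer_
      row[[paste0(cat, "_with_ns")]] <- NA_integer_
    }
  }
  list(summary = row, genes = gene_lists)
}

#' Screen several QTL intervals and add a totals row
#'
#' @param intervals data frame of intervals (see [screen_interval()]).
#' @inheritParams screen_interval
#' @return data frame with one row per interval plus a `Total` row whose
#'   count columns are the column sums (NA-ignoring).
#' @export
screen_intervals <- function(intervals, models, classified, annotations,
                             term_names, keywords = .DEFAULT_KEYWORDS) {
  rows <- lapply(seq_len(nrow(intervals)), function(i)
    screen_interval(intervals[i, ], models, classified, annotations,
                    term_names, keywords)$summary)
  out <- do.call(rbind, rows)
  total <- out[1L, , drop = FALSE]
  total$qtl_id <- "Total"
  total$chromosome <- ""
  total$traits <- ""
  for (col in setdiff(names(out), c("qtl_id", "chromosome", "traits")))
    total[[col]] <- sum(out[[col]], na.rm = TRUE)
  out <- rbind(out, total)
  rownames(out) <- NULL
  out
}

#' Fisher's exact test of indel presence against ecotype
#'
#' Two-sided exact test of independence on a 2x2 table of
#' (insertion present / absent) by (spring / winter) counts.
#'
#' @param table 2x2 matrix of non-negative counts with a positive grand
#'   total and no empty margin.
#' @return two-sided p-value.
#' @export
ecotype_association <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2L, 2L)))
  if (any(table < 0)) stop("counts must be non-negative")
  if (sum(table) == 0) stop("grand total must be positive")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin in 2x2 table")
  fisher.test(table, alternative = "two.sided")$p.value
}
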
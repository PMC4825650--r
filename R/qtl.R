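#' Kosambi map function and its inverse
#'
#' Converts a recombination fraction to genetic distance allowing for
#' crossover interference, d = 25 ln((1 + 2r) / (1 - 2r)) centimorgans, and
#' back, r = (e^(4d/100) - 1) / (2 (e^(4d/100) + 1)). The two functions are
#' exact inverses.
#'
#' @param r recombination fraction(s) in \[0, 0.5).
#' @param d genetic distance(s) in centimorgans (>= 0).
#' @return `kosambi_to_cM`: distance in cM; `kosambi_to_r`: recombination
#'   fraction.
#' @examples
#' kosambi_to_cM(0.25)      # 25 * log(3) ~ 27.47
#' kosambi_to_r(27.465)     # ~ 0.25
#' @export
kosambi_to_cM <- function(r) {
  if (any(r < 0 | r >= 0.5))
    stop("recombination fraction must lie in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname kosambi_to_cM
#' @export
kosambi_to_r <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0")
  e <- exp(4 * d / 100)
  (e - 1) / (2 * (e + 1))
}

#' Conditional probability of the parent-1 allele for a DH line
#'
#' For a doubled-haploid line the genotype at a query position, given the
#' genotypes at the nearest typed flanking markers, follows from the
#' Kosambi-implied recombination fractions of the flanking distances. At a
#' typed marker the probability is 0 or 1; beyond the outermost typed
#' marker the single-flank conditional is used. Missing genotypes are
#' skipped, falling back to the nearest typed markers.
#'
#' @param positions increasing marker positions (cM) on one chromosome.
#' @param genotypes 0/1 (or NA) genotypes of one line at those markers.
#' @param query query position(s) in cM.
#' @return probability (vector) that the line carries the parent-1 allele
#'   (coded 1) at each query position.
#' @export
genotype_probability <- function(positions, genotypes, query) {
  ok <- !is.na(genotypes)
  positions <- positions[ok]
  genotypes <- genotypes[ok]
  if (length(positions) == 0L)
    stop("no typed marker on this chromosome for this line")
  vapply(query, function(q) {
    iL <- findInterval(q, positions)
    if (iL >= 1L && positions[iL] == q) return(as.numeric(genotypes[iL]))
    has_left <- iL >= 1L
    has_right <- iL < length(positions)
    if (has_left && has_right) {
      rL <- kosambi_to_r(q - positions[iL])
      rR <- kosambi_to_r(positions[iL + 1L] - q)
      gL <- genotypes[iL]; gR <- genotypes[iL + 1L]
      tL1 <- if (gL == 1L) 1 - rL else rL
      tR1 <- if (gR == 1L) 1 - rR else rR
      tL0 <- 1 - tL1
      tR0 <- 1 - tR1
      (tL1 * tR1) / (tL1 * tR1 + tL0 * tR0)
    } else if (has_left) {
      rL <- kosambi_to_r(q - positions[iL])
      if (genotypes[iL] == 1L) 1 - rL else rL
    } else {
      rR <- kosambi_to_r(positions[1L] - q)
      if (genotypes[1L] == 1L) 1 - rR else rR
    }
  }, numeric(1))
}

## Expected-genotype matrix on a cM grid. Uses a vectorized path over lines
## when the chromosome has no missing genotypes, otherwise falls back to the
## per-line conditional.
.expected_genotypes <- function(pop, step = 1) {
  map <- pop$map
  G <- pop$genotypes
  grid_rows <- list()
  P_cols <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    pos <- map$pos_cM[idx]
    Gc <- G[, idx, drop = FALSE]
    lo <- min(pos); hi <- max(pos)
    grid <- seq(lo, hi, by = step)
    if (grid[length(grid)] < hi) grid <- c(grid, hi)
    Pch <- matrix(NA_real_, nrow(Gc), length(grid))
    if (!anyNA(Gc)) {
      for (j in seq_along(grid)) {
        q <- grid[j]
        iL <- findInterval(q, pos)
        if (iL >= 1L && pos[iL] == q) {
          Pch[, j] <- as.numeric(Gc[, iL])
        } else {
          gL <- Gc[, iL]; gR <- Gc[, iL + 1L]
          rL <- kosambi_to_r(q - pos[iL])
          rR <- kosambi_to_r(pos[iL + 1L] - q)
          tL1 <- ifelse(gL == 1L, 1 - rL, rL)
          tR1 <- ifelse(gR == 1L, 1 - rR, rR)
          Pch[, j] <- (tL1 * tR1) / (tL1 * tR1 + (1 - tL1) * (1 - tR1))
        }
      }
    } else {
      for (i in seq_len(nrow(Gc)))
        Pch[i, ] <- genotype_probability(pos, Gc[i, ], grid)
    }
    grid_rows[[ch]] <- data.frame(chromosome = ch, pos_cM = grid,
                                  stringsAsFactors = FALSE)
    P_cols[[ch]] <- Pch
  }
  list(grid = do.call(rbind, grid_rows), P = do.call(cbind, P_cols))
}

.lod_from_cor <- function(r2, n) -(n / 2) * log10(pmax(1 - r2, .Machine$double.xmin))

#' Haley-Knott regression QTL scan for a doubled-haploid population
#'
#' At each grid position (1 cM steps by default) the phenotype is regressed
#' on the conditional expectation of the 0/1 genotype given the flanking
#' typed markers; LOD = (n/2) log10(RSS0 / RSS1). Grid points with a
#' monomorphic expected genotype get LOD 0. The peak and its 1.5-LOD-drop
#' support interval (nearest grid points crossing peak - 1.5, on the peak's
#' chromosome) are reported.
#'
#' @param pop a `"dh_population"` (list with `map`, `genotypes`,
#'   `phenotype`); phenotype variance must be positive.
#' @param step grid step in cM (default 1).
#' @param lod_drop support-interval drop (default 1.5).
#' @return list of class `"qtl_scan"`: `grid` (chromosome, pos_cM), `lod`,
#'   `peak_chromosome`, `peak_position`, `peak_lod`, `ci_lo`, `ci_hi`, `n`.
#' @export
hk_scan <- function(pop, step = 1, lod_drop = 1.5) {
  y <- pop$phenotype
  if (var(y) == 0) stop("phenotype variance is zero")
  eg <- .expected_genotypes(pop, step)
  P <- eg$P
  n <- length(y)
  sdp <- apply(P, 2L, sd)
  lod <- numeric(ncol(P))
  use <- sdp > 0
  if (any(use)) {
    r <- suppressWarnings(cor(P[, use, drop = FALSE], y))
    lod[use] <- .lod_from_cor(as.numeric(r)^2, n)
  }
  pk <- which.max(lod)
  peak_chr <- eg$grid$chromosome[pk]
  on_chr <- which(eg$grid$chromosome == peak_chr)
  thr <- lod[pk] - lod_drop
  left <- on_chr[on_chr <= pk]
  below_l <- left[lod[left] < thr]
  ci_lo <- if (length(below_l)) eg$grid$pos_cM[max(below_l)]
           else eg$grid$pos_cM[min(on_chr)]
  right <- on_chr[on_chr >= pk]
  below_r <- right[lod[right] < thr]
  ci_hi <- if (length(below_r)) eg$grid$pos_cM[min(below_r)]
           else eg$grid$pos_cM[max(on_chr)]
  out <- list(grid = eg$grid, lod = lod,
              peak_chromosome = peak_chr,
              peak_position = eg$grid$pos_cM[pk],
              peak_lod = lod[pk],
              ci_lo = ci_lo, ci_hi = ci_hi, n = n)
  class(out) <- "qtl_scan"
  out
}

#' @exportS3Method base::print
print.qtl_scan <- function(x, ...) {
  cat(sprintf("Haley-Knott scan over %d positions (%d lines)\n",
              length(x$lod), x$n))
  cat(sprintf("  peak: LOD %.2f at %s %.1f cM (1.5-LOD interval %.1f-%.1f)\n",
              x$peak_lod, x$peak_chromosome, x$peak_position,
              x$ci_lo, x$ci_hi))
  invisible(x)
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype vector against the genotype rows, rescans, and
#' takes the (1 - alpha) quantile of the per-permutation maximum LOD.
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (>= 100; 1000 matches the study
#'   design).
#' @param alpha genome-wide type-I error rate (default 0.05).
#' @param seed integer seed; the threshold is seed-reproducible.
#' @return list with `threshold`, `max_lods` (per-permutation maxima),
#'   `alpha`, `n_perm`, `seed`.
#' @export
permutation_threshold <- function(pop, n_perm = 1000L, alpha = 0.05,
                                  seed = 1L, step = 1) {
  y <- pop$phenotype
  if (var(y) == 0) stop("phenotype variance is zero")
  stopifnot(n_perm >= 100L, alpha > 0, alpha < 1)
  eg <- .expected_genotypes(pop, step)
  P <- eg$P
  n <- length(y)
  sdp <- apply(P, 2L, sd)
  use <- sdp > 0
  Pc <- scale(P[, use, drop = FALSE])  # centered, unit sd columns
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(k) sample(y), numeric(n))
  Yc <- scale(Y)
  R <- crossprod(Pc, Yc) / (n - 1)  # grid x perm correlation matrix
  max_r2 <- apply(R^2, 2L, max)
  max_lods <- .lod_from_cor(max_r2, n)
  list(threshold = unname(quantile(max_lods, 1 - alpha)),
       max_lods = max_lods, alpha = alpha,
       n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' Genome-wide recombination rate
#'
#' Physical map length divided by genetic map length, in kbp per cM.
#'
#' @param physical_length_bp physical length in bp.
#' @param map_length_cM genetic map length in cM (> 0).
#' @return rate in kbp/cM.
#' @examples
#' recombination_rate(3.05e6, 10)  # 305 kbp/cM
#' @export
recombination_rate <- function(physical_length_bp, map_length_cM) {
  if (any(map_length_cM <= 0)) stop("map length must be > 0")
  (physical_length_bp / 1000) / map_length_cM
}

#' Re-estimate Kosambi distances between adjacent typed markers
#'
#' Estimates the recombination fraction between each pair of adjacent
#' markers as the observed recombinant fraction across DH lines and
#' converts it to centimorgans with the Kosambi function. Fractions at or
#' above 0.5 yield NA (unlinked at this sample size).
#'
#' @param genotypes n_lines x n_markers 0/1 matrix (NA allowed), columns in
#'   map order along one chromosome.
#' @return data frame with `marker_left`, `marker_right`, `r_hat`, `d_cM`.
#' @export
estimate_map_kosambi <- function(genotypes) {
  m <- ncol(genotypes)
  if (m < 2L) stop("need at least two markers")
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("m%d", seq_len(m))
  r_hat <- vapply(seq_len(m - 1L), function(j) {
    a <- genotypes[, j]; b <- genotypes[, j + 1L]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) return(NA_real_)
    mean(a[ok] != b[ok])
  }, numeric(1))
  d <- rep(NA_real_, length(r_hat))
  v <- !is.na(r_hat) & r_hat < 0.5
  d[v] <- kosambi_to_cM(r_hat[v])
  data.frame(marker_left = ids[-m], marker_right = ids[-1L],
             r_hat = r_hat, d_cM = d, stringsAsFactors = FALSE)
}
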
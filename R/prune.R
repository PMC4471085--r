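#' Genotype-dosage linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over pairwise
#' complete observations. Phase is unknown on chip data, so LD is
#' measured on dosages. A pair undefined because one vector is constant
#' after missing-data removal yields 0 (treated as unlinked for
#' pruning).
#'
#' @param dosage_x,dosage_y Equal-length dosage vectors (may contain `NA`).
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosage_x, dosage_y) {
  if (length(dosage_x) != length(dosage_y)) stop("unequal lengths")
  ok <- !is.na(dosage_x) & !is.na(dosage_y)
  if (sum(ok) < 2) stop("fewer than 2 complete pairs")
  x <- dosage_x[ok]
  y <- dosage_y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' LD-pruning configuration
#'
#' Sliding-window pairwise pruning in the style of PLINK's
#' `--indep-pairwise`: windows of `window_snps` markers advanced by
#' `step_snps`, removing one marker from every pair with dosage
#' r-squared above `r2_max`.
#'
#' @param window_snps Window size in SNPs (default 25).
#' @param step_snps Step between windows in SNPs (default 5).
#' @param r2_max Pairwise r-squared threshold (default 0.1).
#' @return A list of class `prune_config`.
#' @export
prune_config <- function(window_snps = 25, step_snps = 5, r2_max = 0.1) {
  if (step_snps > window_snps) stop("step_snps must be <= window_snps")
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (r2_max < 0 || r2_max > 1) stop("r2_max must lie in [0, 1]")
  structure(list(window_snps = as.integer(window_snps),
                 step_snps = as.integer(step_snps), r2_max = r2_max),
            class = "prune_config")
}

# prune survivors within one window (indices into the dosage matrix);
# repeatedly drop the lower-MAF member of the worst pair until clean.
prune_window <- function(d, idx, maf, pos, r2_max) {
  removed <- integer(0)
  while (length(idx) >= 2) {
    r2 <- suppressWarnings(
      stats::cor(d[, idx, drop = FALSE],
                 use = "pairwise.complete.obs")^2
    )
    r2[is.na(r2)] <- 0
    diag(r2) <- 0
    mx <- max(r2)
    if (mx <= r2_max) break
    hit <- which(r2 == mx, arr.ind = TRUE)[1, ]
    i <- idx[hit[1]]
    j <- idx[hit[2]]
    drop <- if (maf[i] < maf[j]) i
            else if (maf[j] < maf[i]) j
            else if (pos[i] > pos[j]) i else j
    removed <- c(removed, drop)
    idx <- setdiff(idx, drop)
  }
  removed
}

#' Prune loci in linkage disequilibrium
#'
#' Per chromosome, windows of `window_snps` surviving markers are slid
#' in steps of `step_snps`; within each window the pair with the highest
#' r-squared above the threshold is found and its lower-MAF member
#' removed (tie: the later map position), repeating until no pair in the
#' window exceeds the threshold. Full sweeps over the genome are
#' repeated until a sweep removes nothing, so the result is a fixed
#' point: re-pruning the output removes no further loci, and no
#' surviving pair within any final window exceeds the threshold.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [prune_config()].
#' @return A list with `genotypes` (pruned matrix) and `kept_ids`
#'   (character vector of surviving locus ids, in map order).
#' @export
prune_ld <- function(gm, cfg = prune_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  ncall <- colSums(!is.na(d))
  p <- ifelse(ncall > 0, colSums(d, na.rm = TRUE) / (2 * ncall), 0)
  maf <- pmin(p, 1 - p)
  pos <- gm$loci$pos
  alive <- rep(TRUE, ncol(d))

  repeat {
    removed_any <- FALSE
    for (ch in unique(gm$loci$chrom)) {
      on_ch <- which(gm$loci$chrom == ch & alive)
      if (length(on_ch) < 2) next
      start <- 1
      while (start <= length(on_ch)) {
        win <- on_ch[start:min(start + cfg$window_snps - 1, length(on_ch))]
        if (length(win) >= 2) {
          rm_idx <- prune_window(d, win, maf, pos, cfg$r2_max)
          if (length(rm_idx) > 0) {
            alive[rm_idx] <- FALSE
            removed_any <- TRUE
            on_ch <- setdiff(on_ch, rm_idx)
          }
        }
        start <- start + cfg$step_snps
      }
    }
    if (!removed_any) break
  }
  keep <- which(alive)
  list(genotypes = gm[, keep], kept_ids = gm$loci$id[keep])
}
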
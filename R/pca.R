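#' Principal component analysis of genotype dosages
#'
#' Missing dosages are mean-imputed per locus; loci are then centered
#' and, by default, scaled by 1/sqrt(pbar(1 - pbar)) where pbar is the
#' pooled allele frequency (the usual genotype-PCA normalization that
#' gives each locus equal expected drift variance). Loci monomorphic
#' after imputation carry no information and are dropped. Scores are
#' obtained from the singular value decomposition of the normalized
#' samples x loci matrix; variance proportions over all components sum
#' to 1.
#'
#' @param gm A [genotype_matrix()] (typically LD-pruned).
#' @param n_components Number of components to return.
#' @param scale If `FALSE`, loci are centered but not scaled.
#' @return A list with `scores` (samples x components, rownames =
#'   sample ids), `proportion_variance` (length `n_components`), and
#'   `populations` (label per sample, for plotting).
#' @export
pca_genotypes <- function(gm, n_components = 10, scale = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- nrow(gm$dosages)
  if (n < 2) stop("need at least 2 samples")
  x <- gm$dosages
  mu <- colMeans(x, na.rm = TRUE)
  na_idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na_idx) > 0) x[na_idx] <- mu[na_idx[, 2]]
  pbar <- mu / 2
  poly <- pbar > 0 & pbar < 1
  x <- x[, poly, drop = FALSE]
  if (ncol(x) == 0) stop("no polymorphic loci for PCA")
  x <- sweep(x, 2, mu[poly])
  if (scale) x <- sweep(x, 2, sqrt(pbar[poly] * (1 - pbar[poly])), "/")
  sv <- svd(x)
  k <- min(n_components, length(sv$d))
  ev <- sv$d^2
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  rownames(scores) <- gm$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores,
       proportion_variance = ev[seq_len(k)] / sum(ev),
       populations = gm$samples$population)
}

#' Per-population genotype proportions at one SNP
#'
#' The genotype-class profile (hom-ref / het / hom-alt) of each
#' population at a single locus, among non-missing calls -- the
#' "stepladder" view of a differentiated SNP.
#'
#' @param gm A [genotype_matrix()].
#' @param locus_id Locus identifier.
#' @return Data frame with one row per population: `population`, `n`
#'   (genotyped individuals), `hom_ref`, `het`, `hom_alt` (proportions
#'   summing to 1; `NA` with `defined = FALSE` if a population has no
#'   calls).
#' @export
genotype_profile <- function(gm, locus_id) {
  stopifnot(inherits(gm, "genotype_matrix"))
  j <- match(locus_id, gm$loci$id)
  if (is.na(j)) stop("locus not found: ", locus_id)
  pops <- unique(gm$samples$population)
  out <- lapply(pops, function(pk) {
    d <- gm$dosages[gm$samples$population == pk, j]
    n <- sum(!is.na(d))
    if (n == 0) {
      data.frame(population = pk, n = 0, hom_ref = NA_real_,
                 het = NA_real_, hom_alt = NA_real_, defined = FALSE)
    } else {
      cnt <- tabulate(d + 1L, nbins = 3)
      data.frame(population = pk, n = n, hom_ref = cnt[1] / n,
                 het = cnt[2] / n, hom_alt = cnt[3] / n, defined = TRUE)
    }
  })
  do.call(rbind, out)
}
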
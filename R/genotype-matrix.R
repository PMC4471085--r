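#' Construct a genotype matrix
#'
#' The central data container of the package: a samples x loci matrix of
#' alternate-allele dosages (0, 1, 2 or `NA` for a missing call) together
#' with an ordered locus map and a population label per sample.
#'
#' @param dosages Integer matrix, samples in rows and loci in columns;
#'   entries must be 0, 1, 2 or `NA`.
#' @param loci Data frame with columns `chrom` (integer autosome code),
#'   `pos` (1-based physical position in bp), `id` (unique locus name),
#'   `ref` and `alt` (allele labels). Must be sorted by (`chrom`, `pos`),
#'   strictly increasing within each chromosome.
#' @param samples Data frame with columns `sample_id` (unique) and
#'   `population` (breed label).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `loci` and `samples`.
#'
#' @examples
#' gm <- genotype_matrix(
#'   dosages = matrix(c(0L, 1L, 2L, 0L), nrow = 2),
#'   loci = data.frame(chrom = 1L, pos = c(100L, 200L),
#'                     id = c("s1", "s2"), ref = "A", alt = "B"),
#'   samples = data.frame(sample_id = c("i1", "i2"),
#'                        population = c("P1", "P2"))
#' )
#' @export
genotype_matrix <- function(dosages, loci, samples) {
  if (!is.matrix(dosages)) stop("`dosages` must be a matrix")
  storage.mode(dosages) <- "integer"
  bad <- !is.na(dosages) & !(dosages %in% 0:2)
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  loci <- as.data.frame(loci)
  samples <- as.data.frame(samples)
  need_l <- c("chrom", "pos", "id", "ref", "alt")
  if (!all(need_l %in% names(loci))) {
    stop("`loci` needs columns: ", paste(need_l, collapse = ", "))
  }
  if (!all(c("sample_id", "population") %in% names(samples))) {
    stop("`samples` needs columns: sample_id, population")
  }
  if (nrow(dosages) != nrow(samples)) {
    stop("nrow(dosages) != number of samples")
  }
  if (ncol(dosages) != nrow(loci)) stop("ncol(dosages) != number of loci")
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample ids")
  if (anyDuplicated(loci$id)) stop("duplicate locus ids")
  o <- order(loci$chrom, loci$pos)
  if (!identical(o, seq_len(nrow(loci)))) {
    stop("loci must be sorted by (chrom, pos)")
  }
  d <- diff(loci$pos)
  same <- diff(loci$chrom) == 0
  if (any(same & d <= 0)) {
    stop("positions must be strictly increasing within a chromosome")
  }
  rownames(dosages) <- samples$sample_id
  colnames(dosages) <- loci$id
  structure(
    list(dosages = dosages, loci = loci, samples = samples),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  pops <- table(x$samples$population)
  cat("genotype_matrix:", nrow(x$dosages), "samples x",
      ncol(x$dosages), "loci\n")
  cat("  chromosomes:", length(unique(x$loci$chrom)),
      " missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(x$dosages))), "\n")
  cat("  populations:",
      paste(sprintf("%s (%d)", names(pops), pops), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i Sample selector (index, logical or sample id).
#' @param j Locus selector (index, logical or locus id).
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selected samples/loci.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosages))
  if (missing(j)) j <- seq_len(ncol(x$dosages))
  if (is.character(i)) i <- match(i, x$samples$sample_id)
  if (is.character(j)) j <- match(j, x$loci$id)
  genotype_matrix(
    x$dosages[i, j, drop = FALSE],
    x$loci[j, , drop = FALSE],
    x$samples[i, , drop = FALSE]
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

# Per-population per-locus summaries used by the F_ST machinery:
# n = genotyped individuals, p = alt-allele frequency, h = observed
# heterozygote frequency. Returns a list of three pop-by-locus matrices.
pop_locus_stats <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- unique(gm$samples$population)
  n <- p <- h <- matrix(
    NA_real_, length(pops), ncol(gm$dosages),
    dimnames = list(pops, gm$loci$id)
  )
  for (k in seq_along(pops)) {
    d <- gm$dosages[gm$samples$population == pops[k], , drop = FALSE]
    nk <- colSums(!is.na(d))
    n[k, ] <- nk
    p[k, ] <- ifelse(nk > 0, colSums(d, na.rm = TRUE) / (2 * nk), NA_real_)
    h[k, ] <- ifelse(nk > 0, colSums(d == 1L, na.rm = TRUE) / nk, NA_real_)
  }
  list(n = n, p = p, h = h)
}
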
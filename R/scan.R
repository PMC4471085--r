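#' Locus-specific branch lengths for three populations
#'
#' Additive three-taxon decomposition of pairwise F_ST: the branch of
#' population A is \eqn{L_A = (\theta_{AB} + \theta_{AC} -
#' \theta_{BC})/2}, and cyclically for B and C. Negative branch lengths
#' are retained. The three branches always sum to half the sum of the
#' three pairwise values.
#'
#' @param theta_AB,theta_AC,theta_BC Pairwise F_ST values (vectors of
#'   equal length for per-locus use, or scalars).
#' @return Matrix with columns `L_A`, `L_B`, `L_C`.
#' @examples
#' lsbl(0.19, 0.13, 0.14)   # -> 0.09, 0.10, 0.04
#' @export
lsbl <- function(theta_AB, theta_AC, theta_BC) {
  cbind(
    L_A = (theta_AB + theta_AC - theta_BC) / 2,
    L_B = (theta_AB + theta_BC - theta_AC) / 2,
    L_C = (theta_AC + theta_BC - theta_AB) / 2
  )
}

#' Per-breed d statistic from standardized pairwise F_ST
#'
#' For breed i, \eqn{d_i = \sum_{j \ne i} (\theta_{ij} -
#' E[\theta_{ij}]) / sd[\theta_{ij}]}, where the expectation and
#' (n-1) standard deviation of each pair's per-locus F_ST are taken
#' over the standardization locus set.
#'
#' @param theta Matrix of per-locus pairwise theta values, one column
#'   per pair; column names of the form `"A-B"`.
#' @param stats Standardization table from [standardization_stats()]
#'   (columns `pair`, `E_fst`, `sd_fst`).
#' @return Matrix with one `d_<breed>` column per breed.
#' @export
d_stat <- function(theta, stats) {
  pairs <- strsplit(colnames(theta), "-", fixed = TRUE)
  breeds <- unique(unlist(pairs))
  idx <- match(colnames(theta), stats$pair)
  if (anyNA(idx)) stop("standardization stats missing for pair: ",
                       colnames(theta)[which(is.na(idx))[1]])
  if (any(stats$sd_fst[idx] <= 0)) {
    stop("zero F_ST standard deviation for pair ",
         stats$pair[idx][which(stats$sd_fst[idx] <= 0)[1]])
  }
  z <- sweep(theta, 2, stats$E_fst[idx])
  z <- sweep(z, 2, stats$sd_fst[idx], "/")
  d <- vapply(breeds, function(b) {
    use <- vapply(pairs, function(p) b %in% p, logical(1))
    rowSums(z[, use, drop = FALSE])
  }, numeric(nrow(theta)))
  matrix(d, nrow = nrow(theta),
         dimnames = list(NULL, paste0("d_", breeds)))
}

#' Standardization constants for the d statistic
#'
#' Mean and sample (n-1) standard deviation of per-locus theta for each
#' pair, over a given locus set.
#'
#' @param theta Per-locus theta matrix (columns = pairs, `"A-B"` names),
#'   rows already restricted to the standardization set.
#' @return Data frame with `pair`, `E_fst`, `sd_fst`, `n_loci`.
#' @export
standardization_stats <- function(theta) {
  data.frame(
    pair = colnames(theta),
    E_fst = colMeans(theta),
    sd_fst = apply(theta, 2, stats::sd),
    n_loci = nrow(theta)
  )
}

#' Per-locus LSBL and d scores for three breeds
#'
#' Runs the three pairwise Weir-Cockerham estimators, restricts to loci
#' where all three pairwise thetas are defined (the complete-case
#' set), computes each breed's LSBL and d per locus, and records the
#' standardization constants. The d standardization uses the same
#' complete-case locus set, so each breed's d has mean exactly zero
#' over it.
#'
#' @param gm A [genotype_matrix()] with exactly three populations
#'   (post-QC, unpruned: the scan uses the full marker set).
#' @param pops Optional explicit ordering of the three labels.
#' @return An object of class `breed_scores`: list with `loci` (map of
#'   the complete-case loci), `theta` (loci x 3 pairs), `lsbl`
#'   (loci x breeds), `d` (loci x breeds), `stand_stats`, `breeds`,
#'   and `n_dropped` (loci discarded as undefined for >= 1 pair).
#' @export
breed_scores <- function(gm, pops = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(pops)) pops <- unique(gm$samples$population)
  if (length(pops) != 3) stop("breed_scores requires exactly 3 populations")
  prs <- utils::combn(pops, 2)
  comp <- lapply(seq_len(3), function(k) {
    fst_components(gm, prs[1, k], prs[2, k])
  })
  theta <- vapply(comp, function(x) x$theta, numeric(ncol(gm$dosages)))
  colnames(theta) <- apply(prs, 2, paste, collapse = "-")
  complete <- rowSums(vapply(comp, function(x) x$defined,
                             logical(ncol(gm$dosages)))) == 3
  theta <- theta[complete, , drop = FALSE]
  loci <- gm$loci[complete, , drop = FALSE]
  rownames(loci) <- NULL
  st <- standardization_stats(theta)
  l <- lsbl(theta[, paste0(pops[1], "-", pops[2])],
            theta[, paste0(pops[1], "-", pops[3])],
            theta[, paste0(pops[2], "-", pops[3])])
  colnames(l) <- paste0("L_", pops)
  d <- d_stat(theta, st)
  colnames(d) <- paste0("d_", pops)
  structure(
    list(loci = loci, theta = theta, lsbl = l, d = d, stand_stats = st,
         breeds = pops, n_dropped = sum(!complete)),
    class = "breed_scores"
  )
}

#' @export
print.breed_scores <- function(x, ...) {
  cat("breed_scores:", nrow(x$loci), "loci x", length(x$breeds),
      "breeds (", x$n_dropped, "loci undefined )\n")
  print(x$stand_stats, row.names = FALSE)
  invisible(x)
}

#' Scan configuration
#'
#' @param window_bp Window width in bp (default 300,000).
#' @param min_snps Minimum scored SNPs per retained window (default 3).
#' @param percentile Empirical percentile defining outlier windows
#'   (default 0.99: the top 1\% of windows).
#' @param bin_size SNPs per bin for the LSBL-ordered correlation profile
#'   (default 5,000).
#' @param window_stat Window aggregator for per-SNP scores: `"mean"`
#'   (default) or `"max"`.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(window_bp = 3e5, min_snps = 3, percentile = 0.99,
                        bin_size = 5000, window_stat = c("mean", "max")) {
  if (percentile <= 0 || percentile >= 1) stop("percentile must be in (0,1)")
  if (min_snps < 1) stop("min_snps must be >= 1")
  structure(list(window_bp = window_bp, min_snps = as.integer(min_snps),
                 percentile = percentile, bin_size = as.integer(bin_size),
                 window_stat = match.arg(window_stat)),
            class = "scan_config")
}

#' Aggregate per-SNP scores into genomic windows
#'
#' Each chromosome is tiled from coordinate 0 with non-overlapping
#' windows of `window_bp` (half-open internally; reported start/end are
#' 1-based inclusive). Every scored locus falls in exactly one window;
#' windows with fewer than `min_snps` scored loci are dropped. Retained
#' windows are numbered consecutively genome-wide in (chrom, start)
#' order. The per-breed window statistic is the mean (or max) of the
#' per-SNP LSBL and d values; the per-breed peak SNP is the locus with
#' the highest per-SNP LSBL in the window (tie: lowest position).
#'
#' @param scores A [breed_scores()] object.
#' @param cfg A [scan_config()].
#' @return Data frame of class `window_table`: `window` (1..N), `chrom`,
#'   `start`, `end` (1-based inclusive bp), `n_snps`, then per breed
#'   `lsbl_<breed>`, `d_<breed>`, `peak_<breed>`.
#' @export
build_windows <- function(scores, cfg = scan_config()) {
  stopifnot(inherits(scores, "breed_scores"))
  loci <- scores$loci
  w <- (loci$pos - 1) %/% cfg$window_bp
  key <- paste(loci$chrom, w)
  grp <- split(seq_len(nrow(loci)), key)
  agg <- if (cfg$window_stat == "mean") mean else max
  rows <- lapply(grp, function(ix) {
    if (length(ix) < cfg$min_snps) return(NULL)
    ch <- loci$chrom[ix[1]]
    w0 <- w[ix[1]]
    row <- data.frame(
      chrom = ch, start = w0 * cfg$window_bp + 1,
      end = (w0 + 1) * cfg$window_bp, n_snps = length(ix)
    )
    for (b in seq_along(scores$breeds)) {
      lv <- scores$lsbl[ix, b]
      row[[paste0("lsbl_", scores$breeds[b])]] <- agg(lv)
      row[[paste0("d_", scores$breeds[b])]] <- agg(scores$d[ix, b])
      peak <- ix[order(-lv, loci$pos[ix])[1]]
      row[[paste0("peak_", scores$breeds[b])]] <- loci$id[peak]
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(chrom = integer(0), start = numeric(0),
                      end = numeric(0), n_snps = integer(0))
    for (b in scores$breeds) {
      out[[paste0("lsbl_", b)]] <- numeric(0)
      out[[paste0("d_", b)]] <- numeric(0)
      out[[paste0("peak_", b)]] <- character(0)
    }
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  out <- cbind(window = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  structure(out, class = c("window_table", "data.frame"),
            breeds = scores$breeds)
}

#' Select empirical outlier windows for one breed and statistic
#'
#' Windows are ranked by the chosen per-breed window statistic in
#' decreasing order and the top ceil((1 - percentile) * N) windows are
#' flagged; ties at the cutoff are broken by the lower window index.
#' With the default 99th percentile, 7,734 windows yield exactly 78
#' selections.
#'
#' @param wt A [build_windows()] table.
#' @param statistic `"lsbl"` or `"d"`.
#' @param breed Breed label.
#' @param cfg A [scan_config()] (supplies `percentile`).
#' @return Sorted integer vector of selected window indices.
#' @export
select_outlier_windows <- function(wt, statistic = c("lsbl", "d"), breed,
                                   cfg = scan_config()) {
  statistic <- match.arg(statistic)
  col <- paste0(statistic, "_", breed)
  if (!col %in% names(wt)) stop("no column ", col, " in window table")
  n <- nrow(wt)
  # round before ceiling: (1 - 0.99) * 100 is 1 + 9e-16 in floating point
  k <- ceiling(round((1 - cfg$percentile) * n, 9))
  ord <- order(-wt[[col]], wt$window)
  sort(wt$window[ord[seq_len(k)]])
}

#' Intersect LSBL and d candidate window lists
#'
#' The merged candidate set of a breed: windows flagged by both
#' statistics.
#'
#' @param lsbl_set,d_set Window index vectors from
#'   [select_outlier_windows()] on the same table.
#' @return Sorted intersection.
#' @export
merge_candidates <- function(lsbl_set, d_set) {
  sort(intersect(lsbl_set, d_set))
}

#' Windows shared between breeds' merged candidate sets
#'
#' @param merged Named list of merged window-index sets, one per breed.
#' @return List with `windows` (data frame: `window`, `breeds`
#'   comma-joined, `n_breeds`; only windows in >= 2 sets) and `pairs`
#'   (data frame of pairwise intersection counts).
#' @export
cross_breed_overlap <- function(merged) {
  if (length(merged) < 2) stop("need >= 2 breeds")
  breeds <- names(merged)
  all_w <- sort(unique(unlist(merged)))
  inwhich <- lapply(all_w, function(w) {
    breeds[vapply(merged, function(s) w %in% s, logical(1))]
  })
  nb <- lengths(inwhich)
  shared <- which(nb >= 2)
  windows <- data.frame(
    window = all_w[shared],
    breeds = vapply(inwhich[shared], paste, character(1), collapse = ","),
    n_breeds = nb[shared]
  )
  prs <- utils::combn(breeds, 2)
  pairs <- data.frame(
    breed_i = prs[1, ], breed_j = prs[2, ],
    n_shared = apply(prs, 2, function(pr) {
      length(intersect(merged[[pr[1]]], merged[[pr[2]]]))
    })
  )
  list(windows = windows, pairs = pairs)
}

#' Agreement between LSBL and d for one breed
#'
#' Overall Pearson correlation of per-SNP LSBL and d values, plus the
#' correlation within consecutive bins of `bin_size` SNPs after sorting
#' loci by LSBL in decreasing order (the "top-bin" agreement profile).
#' A final partial bin is kept if it holds at least 3 loci; a bin with
#' a constant vector gets `NA` with `defined = FALSE`.
#'
#' @param scores A [breed_scores()] object.
#' @param breed Breed label.
#' @param cfg A [scan_config()] (supplies `bin_size`).
#' @return List with `overall_r` and `bins` (data frame: `bin`,
#'   `from_rank`, `to_rank`, `n`, `r`, `defined`).
#' @export
stat_correlation <- function(scores, breed, cfg = scan_config()) {
  stopifnot(inherits(scores, "breed_scores"))
  b <- match(breed, scores$breeds)
  if (is.na(b)) stop("unknown breed: ", breed)
  l <- scores$lsbl[, b]
  d <- scores$d[, b]
  if (length(l) < 3) stop("need >= 3 defined loci")
  overall <- stats::cor(l, d)
  ord <- order(-l)
  l <- l[ord]
  d <- d[ord]
  starts <- seq(1, length(l), by = cfg$bin_size)
  bins <- lapply(seq_along(starts), function(i) {
    ix <- starts[i]:min(starts[i] + cfg$bin_size - 1, length(l))
    if (length(ix) < 3) return(NULL)
    const <- stats::sd(l[ix]) == 0 || stats::sd(d[ix]) == 0
    data.frame(
      bin = i, from_rank = ix[1], to_rank = ix[length(ix)],
      n = length(ix),
      r = if (const) NA_real_ else stats::cor(l[ix], d[ix]),
      defined = !const
    )
  })
  list(overall_r = overall, bins = do.call(rbind, bins))
}
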
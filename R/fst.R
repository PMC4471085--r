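#' Per-locus Weir-Cockerham F_ST variance components for one pair
#'
#' Computes, for every locus, the Weir & Cockerham (1984) analysis-of-
#' variance components for two populations (r = 2): `a` (among
#' populations), `b` (among individuals within populations), `c`
#' (within individuals), and the per-locus estimator
#' theta = a / (a + b + c). Per-locus sample sizes count genotyped
#' individuals only; a locus is *defined* for the pair when both
#' populations have at least two genotyped individuals and
#' a + b + c > 0 (i.e. the locus is not monomorphic across the pair).
#' Negative theta values are retained.
#'
#' With sample sizes n_i, alt-allele frequencies p_i and observed
#' heterozygote frequencies h_i:
#' \deqn{\bar n = \sum n_i / r, \quad
#'       n_c = (r\bar n - \sum n_i^2/(r\bar n))/(r-1)}
#' \deqn{\bar p = \sum n_i p_i/(r\bar n), \quad
#'       s^2 = \sum n_i (p_i-\bar p)^2/((r-1)\bar n), \quad
#'       \bar h = \sum n_i h_i/(r\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'       \left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 -
#'       \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'       \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right],
#'       \quad c = \bar h / 2}
#'
#' @param gm A [genotype_matrix()].
#' @param pop_i,pop_j Population labels.
#' @return An object of class `fst_components`: a data frame with one
#'   row per locus (`chrom`, `pos`, `id`, `a`, `b`, `c`, `theta`,
#'   `defined`) plus attributes `pair` and `n_defined`.
#' @export
fst_components <- function(gm, pop_i, pop_j) {
  stopifnot(inherits(gm, "genotype_matrix"))
  pops <- unique(gm$samples$population)
  for (p in c(pop_i, pop_j)) {
    if (!p %in% pops) stop("unknown population label: ", p)
  }
  st <- pop_locus_stats(gm, c(pop_i, pop_j))
  n1 <- st$n[1, ]; n2 <- st$n[2, ]
  p1 <- st$p[1, ]; p2 <- st$p[2, ]
  h1 <- st$h[1, ]; h2 <- st$h[2, ]
  r <- 2
  nbar <- (n1 + n2) / r
  usable <- n1 >= 2 & n2 >= 2
  nc <- pbar <- s2 <- hbar <- a <- b <- cc <- rep(NA_real_, length(n1))
  u <- which(usable)
  nc[u] <- (r * nbar[u] - (n1[u]^2 + n2[u]^2) / (r * nbar[u])) / (r - 1)
  pbar[u] <- (n1[u] * p1[u] + n2[u] * p2[u]) / (r * nbar[u])
  s2[u] <- (n1[u] * (p1[u] - pbar[u])^2 + n2[u] * (p2[u] - pbar[u])^2) /
    ((r - 1) * nbar[u])
  hbar[u] <- (n1[u] * h1[u] + n2[u] * h2[u]) / (r * nbar[u])
  a[u] <- (nbar[u] / nc[u]) *
    (s2[u] - (1 / (nbar[u] - 1)) *
       (pbar[u] * (1 - pbar[u]) - ((r - 1) / r) * s2[u] - hbar[u] / 4))
  b[u] <- (nbar[u] / (nbar[u] - 1)) *
    (pbar[u] * (1 - pbar[u]) - ((r - 1) / r) * s2[u] -
       ((2 * nbar[u] - 1) / (4 * nbar[u])) * hbar[u])
  cc[u] <- hbar[u] / 2
  tot <- a + b + cc
  defined <- usable & !is.na(tot) & tot > 0
  theta <- ifelse(defined, a / tot, NA_real_)
  out <- data.frame(
    chrom = gm$loci$chrom, pos = gm$loci$pos, id = gm$loci$id,
    a = a, b = b, c = cc, theta = theta, defined = defined
  )
  structure(out, class = c("fst_components", "data.frame"),
            pair = c(pop_i, pop_j), n_defined = sum(defined))
}

#' Genome-wide multilocus F_ST from per-locus components
#'
#' Ratio-of-sums estimator: sum of `a` over defined loci divided by the
#' sum of `a + b + c` (the Weir-Cockerham recommendation for combining
#' loci). A mean-of-ratios variant is available for sensitivity checks.
#'
#' @param components An [fst_components()] table.
#' @param method `"ratio_of_sums"` (default) or `"mean_of_ratios"`.
#' @return A list with `theta` (genome-wide estimate), `n_loci` (defined
#'   loci used) and `pair`.
#' @export
genomewide_fst <- function(components,
                           method = c("ratio_of_sums", "mean_of_ratios")) {
  stopifnot(inherits(components, "fst_components"))
  method <- match.arg(method)
  d <- components[components$defined, , drop = FALSE]
  if (nrow(d) == 0) stop("no defined loci for this pair")
  theta <- if (method == "ratio_of_sums") {
    sum(d$a) / sum(d$a + d$b + d$c)
  } else {
    mean(d$theta)
  }
  list(theta = theta, n_loci = nrow(d), pair = attr(components, "pair"))
}

#' Pairwise genome-wide F_ST for all population pairs
#'
#' @param gm A [genotype_matrix()].
#' @param method Passed to [genomewide_fst()].
#' @return Data frame with one row per unordered pair: `pop_i`, `pop_j`,
#'   `theta`, `n_loci`.
#' @export
pairwise_fst <- function(gm, method = "ratio_of_sums") {
  pops <- unique(gm$samples$population)
  if (length(pops) < 2) stop("need >= 2 populations")
  prs <- utils::combn(pops, 2)
  res <- apply(prs, 2, function(pr) {
    gw <- genomewide_fst(fst_components(gm, pr[1], pr[2]), method)
    data.frame(pop_i = pr[1], pop_j = pr[2], theta = gw$theta,
               n_loci = gw$n_loci)
  })
  do.call(rbind, res)
}

#' Three-branch F_ST phylogeny
#'
#' Builds the unrooted three-taxon star tree whose branch lengths are
#' the additive decomposition of the three pairwise genome-wide F_ST
#' values (the same decomposition that [lsbl()] applies per locus):
#' the branch of population A is (F_AB + F_AC - F_BC)/2, and cyclically.
#' The branch lengths always sum to half the sum of the three pairwise
#' values.
#'
#' @param summary Data frame as returned by [pairwise_fst()] with
#'   exactly three populations, or a named length-3 numeric vector of
#'   pairwise values with names `"A-B"` style.
#' @return Newick string (parseable by [ape::read.tree()]).
#' @export
fst_tree <- function(summary) {
  if (is.data.frame(summary)) {
    pops <- unique(c(summary$pop_i, summary$pop_j))
    if (length(pops) != 3 || nrow(summary) != 3) {
      stop("fst_tree requires exactly three populations")
    }
    get <- function(x, y) {
      hit <- (summary$pop_i == x & summary$pop_j == y) |
        (summary$pop_i == y & summary$pop_j == x)
      summary$theta[hit]
    }
    f_ab <- get(pops[1], pops[2])
    f_ac <- get(pops[1], pops[3])
    f_bc <- get(pops[2], pops[3])
  } else {
    if (length(summary) != 3) stop("need exactly three pairwise values")
    nm <- strsplit(names(summary), "-", fixed = TRUE)
    pops <- unique(unlist(nm))
    if (length(pops) != 3) stop("pair names must involve three populations")
    get <- function(x, y) {
      hit <- vapply(nm, function(p) setequal(p, c(x, y)), logical(1))
      unname(summary[hit])
    }
    f_ab <- get(pops[1], pops[2])
    f_ac <- get(pops[1], pops[3])
    f_bc <- get(pops[2], pops[3])
  }
  br <- lsbl(f_ab, f_ac, f_bc)
  nwk <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 pops[1], br[, 1], pops[2], br[, 2], pops[3], br[, 3])
  ape::read.tree(text = nwk)  # validates
  nwk
}
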
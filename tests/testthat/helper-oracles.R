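# Independent oracle implementations used to cross-check the package's
# vectorized code paths. These deliberately use different algorithms
# (recurrences, scalar loops, naive set algebra) from the implementation.

# HWE exact test via the probability ratio recurrence: relative
# probabilities of successive heterozygote counts are built from
# P(h+2)/P(h) = 4 * nAA(h) * naa(h) / ((h+2)(h+1)), then normalized.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  het <- seq.int(nA %% 2, min(nA, na), by = 2)
  pr <- numeric(length(het))
  pr[1] <- 1
  if (length(het) > 1) {
    for (i in seq_len(length(het) - 1)) {
      h <- het[i]
      hom_a <- (nA - h) / 2
      hom_b <- (na - h) / 2
      pr[i + 1] <- pr[i] * 4 * hom_a * hom_b / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Scalar Weir-Cockerham theta for one locus from genotype count
# triples (AA, Aa, aa) of two populations; dosage counts the second
# allele. Follows the component formulas step by step, one number at
# a time.
wc_theta_scalar <- function(cnt1, cnt2) {
  n1 <- sum(cnt1)
  n2 <- sum(cnt2)
  p1 <- (2 * cnt1[3] + cnt1[2]) / (2 * n1)
  p2 <- (2 * cnt2[3] + cnt2[2]) / (2 * n2)
  h1 <- cnt1[2] / n1
  h2 <- cnt2[2] / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                             hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (tot > 0) a / tot else NA_real_,
       defined = tot > 0)
}

# Two-pass textbook Pearson correlation.
pearson_two_pass <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# A genotype matrix built from explicit per-population genotype count
# triples (one locus): counts list of c(AA, Aa, aa) per population.
gm_from_counts <- function(counts, pops = names(counts)) {
  dos <- unlist(lapply(counts, function(ct) {
    rep(c(0L, 1L, 2L), times = ct)
  }))
  n <- lengths(lapply(counts, function(ct) rep(c(0L, 1L, 2L), ct)))
  genotype_matrix(
    matrix(dos, ncol = 1),
    loci = data.frame(chrom = 1L, pos = 100L, id = "L1",
                      ref = "A", alt = "B"),
    samples = data.frame(
      sample_id = sprintf("s%02d", seq_along(dos)),
      population = rep(pops, times = n)
    )
  )
}

# Small multi-locus genotype matrix with explicit dosage rows.
make_gm <- function(dosages, chrom = NULL, pos = NULL, pops) {
  m <- ncol(dosages)
  if (is.null(chrom)) chrom <- rep(1L, m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(
    dosages,
    loci = data.frame(chrom = chrom, pos = pos,
                      id = paste0("L", seq_len(m)), ref = "A", alt = "B"),
    samples = data.frame(
      sample_id = sprintf("s%02d", seq_len(nrow(dosages))),
      population = pops
    )
  )
}

# Default small neutral simulation shared by several tests.
small_sim <- function(seed = 42, ...) {
  simulate_genotypes(sim_config(
    n_per_pop = 30, n_chrom = 3, chrom_length_bp = 6e6,
    snp_spacing_bp = 5e4, drift_F = 0.1, missing_rate = 0.02,
    seed = seed, ...
  ))
}
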
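#' Simulation configuration
#'
#' Parameters of the three-population Balding-Nichols genotype simulator.
#' The defaults emulate a three-breed sheep SNP-chip panel: breed labels
#' GMM (German Mutton Merino), AWD (African White Dorper) and CMF
#' (Chinese Mongolian fat-tailed) with sample sizes 161/100/61; 26
#' autosomes at roughly one SNP per 50 kb; per-breed drift parameters
#' (0.18, 0.20, 0.08) chosen so the expected pairwise fixation indices,
#' (F_i + F_j)/2 under this model, reproduce a 0.19 / 0.13 / 0.14
#' divergence pattern between the three pairs.
#'
#' @param pop_labels Character vector of >= 3 population names.
#' @param n_per_pop Diploid individuals per population; scalar or one
#'   value per population.
#' @param n_chrom Number of autosomes (default 26).
#' @param chrom_length_bp Length of every chromosome in bp.
#' @param snp_spacing_bp Mean inter-SNP distance in bp; SNP positions are
#'   cumulative exponential gaps with this mean, so a 300-kb window holds
#'   ~6 SNPs at the 50-kb default.
#' @param drift_F Balding-Nichols drift parameter per population, each
#'   strictly in (0, 1); scalar or one value per population.
#' @param n_sweep_regions Number of selected blocks planted per breed
#'   (default 0: neutral genome).
#' @param sweep_width_bp Width of each selected block in bp.
#' @param sweep_shift Allele-frequency displacement delta in (0, 1)
#'   applied to the target breed inside a block.
#' @param min_block_loci Minimum number of simulated loci a planted
#'   block must contain (default 3, the window scan's own minimum SNP
#'   count: a sweep whose footprint covers fewer markers than a window
#'   needs is undetectable by construction and useless for power
#'   evaluation). Placement is resampled until satisfied.
#' @param missing_rate Independent per-genotype missingness probability.
#' @param seed Integer RNG seed; fully determines the output.
#'
#' @return A list of class `sim_config`.
#' @seealso [simulate_genotypes()]
#' @export
sim_config <- function(pop_labels = c("GMM", "AWD", "CMF"),
                       n_per_pop = c(161, 100, 61),
                       n_chrom = 26,
                       chrom_length_bp = 9e7,
                       snp_spacing_bp = 5e4,
                       drift_F = c(0.18, 0.20, 0.08),
                       n_sweep_regions = 0,
                       sweep_width_bp = 3e5,
                       sweep_shift = 0.45,
                       min_block_loci = 3,
                       missing_rate = 0.01,
                       seed = 1L) {
  if (length(pop_labels) < 3) stop("need >= 3 population labels")
  if (anyDuplicated(pop_labels)) stop("duplicate population labels")
  n_per_pop <- rep_len(as.integer(n_per_pop), length(pop_labels))
  if (any(n_per_pop < 2)) {
    stop("n_per_pop must be >= 2 in every population (F_ST undefined)")
  }
  drift_F <- rep_len(as.numeric(drift_F), length(pop_labels))
  if (any(drift_F <= 0 | drift_F >= 1)) stop("drift_F must lie in (0, 1)")
  if (missing_rate < 0 || missing_rate > 1) {
    stop("missing_rate must lie in [0, 1]")
  }
  if (n_sweep_regions > 0) {
    if (sweep_shift <= 0 || sweep_shift >= 1) {
      stop("sweep_shift must lie in (0, 1)")
    }
    if (sweep_width_bp > chrom_length_bp) {
      stop("sweep block wider than a chromosome")
    }
  }
  if (n_chrom < 1 || chrom_length_bp <= 0 || snp_spacing_bp <= 0) {
    stop("invalid genome dimensions")
  }
  structure(
    list(
      pop_labels = as.character(pop_labels), n_per_pop = n_per_pop,
      n_chrom = as.integer(n_chrom), chrom_length_bp = chrom_length_bp,
      snp_spacing_bp = snp_spacing_bp, drift_F = drift_F,
      n_sweep_regions = as.integer(n_sweep_regions),
      sweep_width_bp = sweep_width_bp, sweep_shift = sweep_shift,
      min_block_loci = as.integer(min_block_loci),
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate three-population SNP genotypes with planted sweeps
#'
#' Draws diploid biallelic genotypes under the Balding-Nichols drift
#' model. For each locus an ancestral allele frequency p is drawn
#' uniformly on \[0.05, 0.95\]; population k's frequency is drawn from
#' Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k), a parameterization whose
#' fixation index equals F_k. Optionally, contiguous "sweep" blocks are
#' planted per breed: inside a block the target breed's frequency is
#' replaced by the ancestral p displaced by `sweep_shift` toward the
#' boundary farther from p (up when p <= 0.5, down otherwise), clamped
#' to \[0.01, 0.99\], so every in-block locus diverges by the full
#' displacement.
#' Genotypes are Binomial(2, p_k) draws; missing calls are planted
#' independently at `missing_rate`.
#'
#' A single RNG stream seeded from `config$seed` is consumed in a fixed
#' order (positions, ancestral frequencies, population frequencies,
#' sweep placement, genotypes, missingness), so the same configuration
#' reproduces the same data exactly.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `truth` (data frame of planted blocks: `population`, `chrom`,
#'   `start`, `end`, `delta`, `n_loci`; zero rows for a neutral genome).
#' @examples
#' sim <- simulate_genotypes(sim_config(
#'   n_per_pop = 20, n_chrom = 2, chrom_length_bp = 5e6, seed = 42
#' ))
#' sim$genotypes
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  npop <- length(cfg$pop_labels)

  # SNP positions: exponential gaps, mean snp_spacing_bp, per chromosome
  chrom <- integer(0)
  pos <- numeric(0)
  for (ch in seq_len(cfg$n_chrom)) {
    expected <- ceiling(cfg$chrom_length_bp / cfg$snp_spacing_bp * 1.4) + 20
    gaps <- stats::rexp(expected, rate = 1 / cfg$snp_spacing_bp)
    p <- cumsum(gaps)
    p <- floor(p[p < cfg$chrom_length_bp]) + 1
    p <- unique(p)
    chrom <- c(chrom, rep.int(ch, length(p)))
    pos <- c(pos, p)
  }
  n_loci <- length(pos)
  if (n_loci == 0) stop("no loci generated; check genome dimensions")

  p_anc <- stats::runif(n_loci, 0.05, 0.95)

  # per-population drifted frequencies (frequencies before sweep shifts)
  pk <- matrix(NA_real_, npop, n_loci)
  for (k in seq_len(npop)) {
    f <- cfg$drift_F[k]
    pk[k, ] <- stats::rbeta(n_loci, p_anc * (1 - f) / f,
                            (1 - p_anc) * (1 - f) / f)
  }

  # sweep placement
  truth <- data.frame(
    population = character(0), chrom = integer(0), start = numeric(0),
    end = numeric(0), delta = numeric(0), n_loci = integer(0)
  )
  if (cfg$n_sweep_regions > 0) {
    for (k in seq_len(npop)) {
      placed <- 0
      tries <- 0
      while (placed < cfg$n_sweep_regions) {
        tries <- tries + 1
        if (tries > 1000 * cfg$n_sweep_regions) {
          stop("could not place sweep blocks containing loci; ",
               "increase SNP density or chromosome length")
        }
        ch <- sample.int(cfg$n_chrom, 1)
        start <- floor(stats::runif(1, 1,
                                    cfg$chrom_length_bp - cfg$sweep_width_bp))
        end <- start + cfg$sweep_width_bp - 1
        hit <- which(chrom == ch & pos >= start & pos <= end)
        if (length(hit) < cfg$min_block_loci) next
        # avoid stacking two blocks of the same breed on the same loci
        if (nrow(truth) > 0 &&
            any(truth$population == cfg$pop_labels[k] &
                truth$chrom == ch &
                truth$start <= end & truth$end >= start)) next
        pk[k, hit] <- ifelse(
          p_anc[hit] <= 0.5,
          pmin(p_anc[hit] + cfg$sweep_shift, 0.99),
          pmax(p_anc[hit] - cfg$sweep_shift, 0.01)
        )
        truth <- rbind(truth, data.frame(
          population = cfg$pop_labels[k], chrom = ch, start = start,
          end = end, delta = cfg$sweep_shift, n_loci = length(hit)
        ))
        placed <- placed + 1
      }
    }
    truth <- truth[order(match(truth$population, cfg$pop_labels),
                         truth$chrom, truth$start), , drop = FALSE]
    rownames(truth) <- NULL
  }

  # genotypes: Binomial(2, p_k) per individual
  n_total <- sum(cfg$n_per_pop)
  dos <- matrix(NA_integer_, n_total, n_loci)
  row0 <- 0
  for (k in seq_len(npop)) {
    nk <- cfg$n_per_pop[k]
    g <- stats::rbinom(nk * n_loci, 2, rep(pk[k, ], each = nk))
    dos[row0 + seq_len(nk), ] <- matrix(as.integer(g), nk, n_loci)
    row0 <- row0 + nk
  }

  if (cfg$missing_rate > 0) {
    dos[stats::runif(length(dos)) < cfg$missing_rate] <- NA_integer_
  }

  samples <- data.frame(
    sample_id = sprintf("%s_%03d",
                        rep(cfg$pop_labels, cfg$n_per_pop),
                        unlist(lapply(cfg$n_per_pop, seq_len))),
    population = rep(cfg$pop_labels, cfg$n_per_pop)
  )
  loci <- data.frame(
    chrom = chrom, pos = as.integer(pos),
    id = sprintf("snp_%d_%d", chrom, as.integer(pos)),
    ref = "A", alt = "B"
  )
  gm <- genotype_matrix(dos, loci, samples)
  list(genotypes = gm, truth = truth)
}

#' Write a sweep-truth table to TSV
#'
#' @param truth Truth data frame from [simulate_genotypes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
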
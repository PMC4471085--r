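#' Exact test of Hardy-Weinberg proportions
#'
#' Exact conditional test: given the observed allele counts, the
#' probability of each attainable heterozygote count is computed and the
#' two-sided p-value is the sum of the probabilities of all
#' configurations no more probable than the observed one (plain exact
#' test, no mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (nonnegative, total >= 1).
#' @return Exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(10, 1, 10)   # heterozygote deficit
#' hwe_exact_test(5, 0, 0)     # monomorphic: p = 1
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  het <- seq.int(nA %% 2, min(nA, na), by = 2)
  # log P(h het | allele counts) up to a constant:
  #   2^h * n! / ((nA-h)/2)! / h! / ((na-h)/2)!
  lp <- het * log(2) - lgamma((nA - het) / 2 + 1) - lgamma(het + 1) -
    lgamma((na - het) / 2 + 1)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

#' Quality-control configuration
#'
#' Thresholds follow common SNP-chip practice: loci are retained when
#' the pooled minor allele frequency exceeds `maf_min`, the pooled
#' Hardy-Weinberg exact p-value exceeds `hwe_p_min`, and the chromosome
#' is an autosome (1..26). All comparisons are strict (`>`).
#'
#' @param maf_min Minimum minor allele frequency (exclusive), default 0.01.
#' @param hwe_p_min Minimum HWE exact p-value (exclusive), default 1e-6.
#' @param hwe_scope `"pooled"` (default) tests Hardy-Weinberg on the
#'   pooled sample; `"per_population"` tests within each population and
#'   fails a locus when any population falls at or below the threshold.
#'   The pooled test also rejects strongly differentiated loci (Wahlund
#'   effect), which biases genome-wide divergence downward in highly
#'   structured panels; the per-population scope avoids that.
#' @param autosomes_only Keep only chromosomes 1..26 (default `TRUE`).
#' @param call_rate_min Optional minimum per-locus call rate
#'   (`NULL` = off).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, hwe_p_min = 1e-6,
                      hwe_scope = c("pooled", "per_population"),
                      autosomes_only = TRUE, call_rate_min = NULL) {
  for (v in c(maf_min, hwe_p_min, call_rate_min)) {
    if (!is.null(v) && (v < 0 || v > 1)) stop("thresholds must lie in [0, 1]")
  }
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 hwe_scope = match.arg(hwe_scope),
                 autosomes_only = isTRUE(autosomes_only),
                 call_rate_min = call_rate_min),
            class = "qc_config")
}

#' Apply quality-control filters to a genotype panel
#'
#' Loci failing any criterion are removed; the report attributes each
#' removal to the first failing criterion, evaluated in the order
#' MAF, HWE, autosome (then call rate if enabled). MAF and the HWE test
#' are computed on the pooled sample across populations.
#'
#' @param gm A [genotype_matrix()].
#' @param cfg A [qc_config()].
#' @return A list with `genotypes` (filtered matrix) and `report`
#'   (data frame of per-criterion removal counts).
#' @export
apply_qc <- function(gm, cfg = qc_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosages
  ncall <- colSums(!is.na(d))
  p <- ifelse(ncall > 0, colSums(d, na.rm = TRUE) / (2 * ncall), 0)
  maf <- pmin(p, 1 - p)
  fail_maf <- !(maf > cfg$maf_min)

  hwe_block <- function(dd) {
    # memoized exact test over a dosage block (samples x loci)
    ncall_b <- colSums(!is.na(dd))
    n2 <- colSums(dd == 2L, na.rm = TRUE)
    n1 <- colSums(dd == 1L, na.rm = TRUE)
    n0 <- ncall_b - n2 - n1
    p <- rep(1, ncol(dd))
    todo <- which(ncall_b > 0)
    if (length(todo) > 0) {
      key <- paste(n0[todo], n1[todo], n2[todo])
      uk <- !duplicated(key)
      pv <- vapply(todo[uk], function(j) {
        hwe_exact_test(n0[j], n1[j], n2[j])
      }, numeric(1))
      p[todo] <- pv[match(key, key[uk])]
    }
    p
  }
  hwe_p <- if (cfg$hwe_scope == "pooled") {
    hwe_block(d)
  } else {
    per_pop <- vapply(unique(gm$samples$population), function(pk) {
      hwe_block(d[gm$samples$population == pk, , drop = FALSE])
    }, numeric(ncol(d)))
    apply(per_pop, 1, min)
  }
  fail_hwe <- !fail_maf & !(hwe_p > cfg$hwe_p_min)

  fail_auto <- if (cfg$autosomes_only) {
    !fail_maf & !fail_hwe & !(gm$loci$chrom %in% 1:26)
  } else rep(FALSE, ncol(d))

  fail_call <- if (!is.null(cfg$call_rate_min)) {
    cr <- ncall / nrow(d)
    !fail_maf & !fail_hwe & !fail_auto & !(cr > cfg$call_rate_min)
  } else rep(FALSE, ncol(d))

  keep <- !(fail_maf | fail_hwe | fail_auto | fail_call)
  if (!any(keep)) {
    stop("no loci survive QC; review maf_min/hwe_p_min thresholds")
  }
  report <- data.frame(
    criterion = c("maf", "hwe", "autosome", "call_rate", "retained"),
    n = c(sum(fail_maf), sum(fail_hwe), sum(fail_auto), sum(fail_call),
          sum(keep))
  )
  list(genotypes = gm[, which(keep)], report = report)
}
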
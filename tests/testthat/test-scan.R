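test_that("lsbl reproduces the printed worked example and its identities", {
  # pairwise (GMM-AWD, GMM-CMF, AWD-CMF) = (0.19, 0.13, 0.14)
  br <- lsbl(0.19, 0.13, 0.14)
  expect_equal(unname(br[1, ]), c(0.09, 0.10, 0.04), tolerance = 1e-12)

  expect_equal(unname(lsbl(0.2, 0.2, 0.2)[1, ]), rep(0.1, 3))

  set.seed(8)
  t3 <- matrix(runif(300, -0.1, 1), ncol = 3)
  br <- lsbl(t3[, 1], t3[, 2], t3[, 3])
  expect_equal(rowSums(br), rowSums(t3) / 2, tolerance = 1e-12)
})

test_that("d is centered and matches a two-pass hand computation", {
  theta <- cbind(
    "A-B" = c(0.10, 0.20, 0.15, 0.05, 0.50),
    "A-C" = c(0.12, 0.18, 0.30, 0.02, 0.38),
    "B-C" = c(0.08, 0.22, 0.12, 0.09, 0.49)
  )
  st <- standardization_stats(theta)
  expect_equal(st$E_fst, unname(colMeans(theta)))
  expect_equal(st$sd_fst, unname(apply(theta, 2, sd)))  # n-1 denominator

  d <- d_stat(theta, st)
  # hand computation: standardized sums over the two pairs per breed
  z <- scale(theta)  # two-pass center/scale, n-1 sd
  expect_equal(unname(d[, "d_A"]), unname(z[, "A-B"] + z[, "A-C"]),
               tolerance = 1e-12)
  expect_equal(unname(d[, "d_B"]), unname(z[, "A-B"] + z[, "B-C"]),
               tolerance = 1e-12)
  expect_equal(unname(d[, "d_C"]), unname(z[, "A-C"] + z[, "B-C"]),
               tolerance = 1e-12)
  expect_true(all(abs(colMeans(d)) < 1e-8))

  # locus where every theta equals its pair mean -> d = 0
  at_mean <- matrix(colMeans(theta), 1,
                    dimnames = list(NULL, colnames(theta)))
  expect_equal(unname(d_stat(at_mean, st)[1, ]), rep(0, 3))

  st_bad <- st
  st_bad$sd_fst[2] <- 0
  expect_error(d_stat(theta, st_bad), "A-C")
})

test_that("breed scores satisfy the lsbl sum identity and d centering", {
  sim <- small_sim(seed = 25)
  gm <- apply_qc(sim$genotypes)$genotypes
  sc <- breed_scores(gm)
  expect_equal(rowSums(sc$lsbl), rowSums(sc$theta) / 2, tolerance = 1e-12)
  expect_true(all(abs(colMeans(sc$d)) < 1e-8))
})

test_that("windows aggregate per-SNP scores correctly", {
  sim <- small_sim(seed = 26)
  gm <- apply_qc(sim$genotypes)$genotypes
  sc <- breed_scores(gm)
  wt <- build_windows(sc, scan_config())
  expect_true(all(wt$n_snps >= 3))
  expect_equal(wt$window, seq_len(nrow(wt)))
  expect_true(all(wt$end - wt$start + 1 == 3e5))

  # brute-force recomputation of every window mean and peak
  b <- sc$breeds[1]
  for (r in sample(nrow(wt), min(20, nrow(wt)))) {
    ix <- which(sc$loci$chrom == wt$chrom[r] &
                  sc$loci$pos >= wt$start[r] & sc$loci$pos <= wt$end[r])
    expect_equal(wt$n_snps[r], length(ix))
    expect_equal(wt[[paste0("lsbl_", b)]][r], mean(sc$lsbl[ix, 1]))
    expect_equal(wt[[paste0("d_", b)]][r], mean(sc$d[ix, 1]))
    pk <- ix[order(-sc$lsbl[ix, 1], sc$loci$pos[ix])[1]]
    expect_equal(wt[[paste0("peak_", b)]][r], sc$loci$id[pk])
  }
})

test_that("underpopulated tiling yields zero retained windows", {
  theta <- cbind("A-B" = rep(0.1, 3), "A-C" = rep(0.1, 3),
                 "B-C" = rep(0.1, 3))
  sc <- structure(list(
    loci = data.frame(chrom = 1L, pos = c(10000L, 20000L, 310000L),
                      id = paste0("L", 1:3), ref = "A", alt = "B"),
    theta = theta, lsbl = lsbl(theta[, 1], theta[, 2], theta[, 3]),
    d = matrix(0, 3, 3, dimnames = list(NULL, c("d_A", "d_B", "d_C"))),
    breeds = c("A", "B", "C"), n_dropped = 0
  ), class = "breed_scores")
  colnames(sc$lsbl) <- c("L_A", "L_B", "L_C")
  wt <- build_windows(sc, scan_config(min_snps = 3))
  expect_equal(nrow(wt), 0)

  # all six loci in one window with constant score -> one window, mean v
  sc$loci <- data.frame(chrom = 1L, pos = seq(1000L, 251000L, by = 50000L),
                        id = paste0("L", 1:6), ref = "A", alt = "B")
  sc$theta <- theta[rep(1, 6), ]
  sc$lsbl <- lsbl(sc$theta[, 1], sc$theta[, 2], sc$theta[, 3])
  sc$d <- matrix(0, 6, 3, dimnames = list(NULL, c("d_A", "d_B", "d_C")))
  wt <- build_windows(sc, scan_config())
  expect_equal(nrow(wt), 1)
  expect_equal(wt$lsbl_A, 0.05)
  expect_equal(wt$n_snps, 6)
})

test_that("the percentile rule selects ceil(0.01 N) windows with tie rules", {
  mk_wt <- function(vals) {
    structure(
      data.frame(window = seq_along(vals), chrom = 1L,
                 start = seq_along(vals), end = seq_along(vals),
                 n_snps = 3L, lsbl_A = vals, d_A = vals),
      breeds = "A", class = c("window_table", "data.frame")
    )
  }
  set.seed(9)
  expect_length(select_outlier_windows(mk_wt(runif(100)), "lsbl", "A"), 1)
  sel <- select_outlier_windows(mk_wt(rep(1, 200)), "lsbl", "A")
  expect_equal(sel, 1:2)  # ties broken by lower window index
  for (n in c(1, 7, 99, 1000)) {
    expect_length(select_outlier_windows(mk_wt(rnorm(n)), "d", "A"),
                  ceiling(0.01 * n))
  }
  # top-k really are the largest values
  v <- rnorm(500)
  sel <- select_outlier_windows(mk_wt(v), "lsbl", "A")
  expect_setequal(sel, order(v, decreasing = TRUE)[1:5])
})

test_that("merged candidates are the intersection; overlaps are set algebra", {
  expect_equal(merge_candidates(c(1, 2, 3), c(2, 3, 4)), c(2, 3))
  expect_length(merge_candidates(1:3, 4:6), 0)
  expect_equal(merge_candidates(1:3, 1:3), 1:3)

  set.seed(10)
  sets <- list(A = sample(100, 30), B = sample(100, 30),
               C = sample(100, 30))
  ov <- cross_breed_overlap(sets)
  for (r in seq_len(nrow(ov$pairs))) {
    expect_equal(
      ov$pairs$n_shared[r],
      length(intersect(sets[[ov$pairs$breed_i[r]]],
                       sets[[ov$pairs$breed_j[r]]]))
    )
  }
  in2 <- Filter(function(w) {
    sum(vapply(sets, function(s) w %in% s, logical(1))) >= 2
  }, 1:100)
  expect_setequal(ov$windows$window, in2)
  expect_equal(nrow(cross_breed_overlap(list(A = 1:3, B = 4:6))$windows), 0)
})

test_that("lsbl-d correlation is exact for affine scores and near zero for noise", {
  sim <- small_sim(seed = 27)
  gm <- apply_qc(sim$genotypes)$genotypes
  sc <- breed_scores(gm)
  b <- sc$breeds[1]

  affine <- sc
  affine$d[, 1] <- 3 * affine$lsbl[, 1] + 0.5
  expect_equal(stat_correlation(affine, b)$overall_r, 1)

  set.seed(11)
  noise <- sc
  noise$d[, 1] <- rnorm(nrow(noise$d))
  r <- stat_correlation(noise, b, scan_config(bin_size = 100))
  expect_lt(abs(r$overall_r), 0.1)
  expect_equal(r$overall_r,
               pearson_two_pass(noise$lsbl[, 1], noise$d[, 1]),
               tolerance = 1e-12)

  # bins partition ranks in LSBL-descending order
  expect_equal(sum(r$bins$n), nrow(sc$loci))
  expect_true(all(diff(r$bins$from_rank) == 100))
})

test_that("the scan is invariant to chromosome relabeling order", {
  sim <- small_sim(seed = 28)
  gm <- apply_qc(sim$genotypes)$genotypes
  sc <- breed_scores(gm)
  wt <- build_windows(sc)
  sets <- candidate_sets(wt)

  # reverse chromosome ids; windows renumber but flags map consistently
  remap <- gm
  nch <- max(gm$loci$chrom)
  remap$loci$chrom <- nch + 1L - remap$loci$chrom
  ord <- order(remap$loci$chrom, remap$loci$pos)
  remap <- genotype_matrix(remap$dosages[, ord],
                           remap$loci[ord, ], remap$samples)
  sc2 <- breed_scores(remap)
  wt2 <- build_windows(sc2)
  sets2 <- candidate_sets(wt2)
  key <- function(w, t) paste(t$chrom[match(w, t$window)],
                              t$start[match(w, t$window)])
  for (b in names(sets$merged)) {
    k1 <- key(sets$merged[[b]], wt)
    k1 <- sub("^", "", k1)
    # translate original chrom to relabeled chrom for comparison
    parts <- strsplit(k1, " ")
    k1t <- vapply(parts, function(z) {
      paste(nch + 1L - as.integer(z[1]), z[2])
    }, character(1))
    expect_setequal(k1t, key(sets2$merged[[b]], wt2))
  }
})
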
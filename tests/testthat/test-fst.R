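test_that("fixed difference gives theta = 1, shared fixation is undefined", {
  gm <- gm_from_counts(list(P1 = c(0, 0, 8), P2 = c(8, 0, 0)))
  comp <- fst_components(gm, "P1", "P2")
  expect_identical(comp$theta, 1)
  expect_equal(comp$a, 0.5)
  expect_equal(comp$b, 0)
  expect_equal(comp$c, 0)

  gm2 <- gm_from_counts(list(P1 = c(8, 0, 0), P2 = c(8, 0, 0)))
  comp2 <- fst_components(gm2, "P1", "P2")
  expect_false(comp2$defined)
  expect_true(is.na(comp2$theta))
})

test_that("components match the scalar oracle on a hand fixture", {
  c1 <- c(3, 1, 0)
  c2 <- c(0, 2, 2)
  gm <- gm_from_counts(list(P1 = c1, P2 = c2))
  comp <- fst_components(gm, "P1", "P2")
  o <- wc_theta_scalar(c1, c2)
  expect_equal(comp$a, o$a, tolerance = 1e-12)
  expect_equal(comp$b, o$b, tolerance = 1e-12)
  expect_equal(comp$c, o$c, tolerance = 1e-12)
  expect_equal(comp$theta, o$theta, tolerance = 1e-12)
})

test_that("vectorized theta equals the scalar formula on random loci", {
  set.seed(6)
  sim <- simulate_genotypes(sim_config(
    n_per_pop = 25, n_chrom = 2, chrom_length_bp = 2.5e7,
    drift_F = 0.15, missing_rate = 0.03, seed = 6
  ))
  gm <- sim$genotypes
  pops <- unique(gm$samples$population)
  comp <- fst_components(gm, pops[1], pops[2])
  expect_gt(nrow(comp), 900)
  d1 <- gm$dosages[gm$samples$population == pops[1], ]
  d2 <- gm$dosages[gm$samples$population == pops[2], ]
  for (j in seq_len(ncol(gm$dosages))) {
    cnt1 <- tabulate(d1[, j] + 1L, 3)
    cnt2 <- tabulate(d2[, j] + 1L, 3)
    o <- wc_theta_scalar(cnt1, cnt2)
    if (comp$defined[j]) {
      expect_equal(comp$theta[j], o$theta, tolerance = 1e-10)
    } else {
      expect_true(!o$defined || sum(cnt1) < 2 || sum(cnt2) < 2)
    }
  }
})

test_that("estimator is symmetric and label-equivariant", {
  sim <- small_sim(seed = 23)
  gm <- sim$genotypes
  pops <- unique(gm$samples$population)
  ij <- fst_components(gm, pops[1], pops[2])
  ji <- fst_components(gm, pops[2], pops[1])
  expect_identical(ij$theta, ji$theta)
  expect_identical(ij$a, ji$a)

  # relabel populations jointly: summaries permute consistently
  relab <- gm
  map <- c(X = pops[2], Y = pops[3], Z = pops[1])
  relab$samples$population <-
    names(map)[match(gm$samples$population, map)]
  pw_orig <- pairwise_fst(gm)
  pw_new <- pairwise_fst(relab)
  for (r in seq_len(3)) {
    orig_pair <- sort(unname(c(map[pw_new$pop_i[r]], map[pw_new$pop_j[r]])))
    hit <- which(
      apply(pw_orig[, 1:2], 1,
            function(z) identical(sort(unname(z)), orig_pair))
    )
    expect_equal(pw_new$theta[r], pw_orig$theta[hit])
  }
})

test_that("genome-wide theta is a ratio of sums", {
  gm <- gm_from_counts(list(P1 = c(0, 0, 8), P2 = c(8, 0, 0)))
  comp <- fst_components(gm, "P1", "P2")
  expect_equal(genomewide_fst(comp)$theta, comp$theta[1])

  # two loci with components (1,0,1) and (0,0,2) -> 1/4, not mean 1/4+0
  fake <- comp[c(1, 1), ]
  fake$a <- c(1, 0)
  fake$b <- c(0, 0)
  fake$c <- c(1, 2)
  fake$theta <- fake$a / (fake$a + fake$b + fake$c)
  fake$defined <- TRUE
  attr(fake, "pair") <- c("P1", "P2")
  class(fake) <- c("fst_components", "data.frame")
  expect_equal(genomewide_fst(fake)$theta, 0.25)
  expect_equal(genomewide_fst(fake, "mean_of_ratios")$theta, 0.25)
  expect_error(genomewide_fst(fake[0, ]), "no defined loci")
})

test_that("balding-nichols simulation recovers its drift parameter", {
  sim <- simulate_genotypes(sim_config(
    n_per_pop = 60, n_chrom = 6, chrom_length_bp = 1e7,
    snp_spacing_bp = 1e4, drift_F = 0.15, missing_rate = 0, seed = 9
  ))
  pw <- pairwise_fst(sim$genotypes)
  expect_true(all(abs(pw$theta - 0.15) < 0.015))
})

test_that("the three-branch tree decomposes printed pairwise values", {
  pw <- data.frame(pop_i = c("GMM", "GMM", "AWD"),
                   pop_j = c("AWD", "CMF", "CMF"),
                   theta = c(0.19, 0.13, 0.14), n_loci = 1)
  nwk <- fst_tree(pw)
  tr <- ape::read.tree(text = nwk)
  br <- setNames(tr$edge.length, tr$tip.label)
  expect_equal(unname(br[c("GMM", "AWD", "CMF")]), c(0.09, 0.10, 0.04),
               tolerance = 1e-12)

  # symmetric input: all branches f/2; branch sum = sum(theta)/2
  pw$theta <- 0.2
  tr2 <- ape::read.tree(text = fst_tree(pw))
  expect_equal(tr2$edge.length, rep(0.1, 3))
  set.seed(7)
  for (i in 1:10) {
    pw$theta <- runif(3)
    tr3 <- ape::read.tree(text = fst_tree(pw))
    expect_equal(sum(tr3$edge.length), sum(pw$theta) / 2,
                 tolerance = 1e-12)
  }
  expect_error(fst_tree(pw[1:2, ]), "three")
})

test_that("unknown population labels are rejected", {
  sim <- small_sim(seed = 24)
  expect_error(fst_components(sim$genotypes, "GMM", "nope"), "nope")
})
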
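test_that("bed coordinates convert to 1-based inclusive", {
  dir <- withr::local_tempdir()
  bed <- file.path(dir, "g.bed")
  writeLines(c("1\t999\t2000\tG1", "2\t0\t100\tG2"), bed)
  g <- read_gene_intervals(bed)
  expect_equal(g$start, c(1000, 1))
  expect_equal(g$end, c(2000, 100))
  expect_equal(g$gene, c("G1", "G2"))
})

test_that("gff3 keeps only the requested feature type", {
  dir <- withr::local_tempdir()
  gff <- file.path(dir, "g.gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=gene1;Name=G1",
    "1\tsrc\tmRNA\t1000\t2000\t.\t+\t.\tID=rna1;Parent=gene1"
  ), gff)
  g <- read_gene_intervals(gff)
  expect_equal(nrow(g), 1)
  expect_equal(g$gene, "G1")
  expect_equal(g$start, 1000)

  empty <- file.path(dir, "empty.bed")
  writeLines(character(0), empty)
  expect_warning(g0 <- read_gene_intervals(empty), "no intervals")
  expect_equal(nrow(g0), 0)
})

# shared fixture: 2 windows on chrom 1, 1 on chrom 2, hand-placed genes
ann_fixture <- function() {
  wt <- structure(
    data.frame(
      window = 1:3, chrom = c(1L, 1L, 2L),
      start = c(1, 300001, 1), end = c(300000, 600000, 300000),
      n_snps = 3L,
      lsbl_A = c(0.5, 0.4, 0.1), d_A = c(5, 4, 1),
      peak_A = c("s1", "s2", "s3"),
      lsbl_B = c(0.1, 0.1, 0.6), d_B = c(1, 1, 6),
      peak_B = c("s1", "s2", "s3")
    ),
    breeds = c("A", "B"), class = c("window_table", "data.frame")
  )
  genes <- data.frame(
    chrom = c("1", "1", "1", "2", "2"),
    start = c(100, 299900, 700000, 50, 360000),
    end = c(200, 300100, 800000, 80, 370000),
    strand = "+",
    gene = c("IN_W1", "SPAN_W1_W2", "NOWHERE", "IN_W3", "NEAR_PEAK3")
  )
  scores <- list(loci = data.frame(
    chrom = c(1L, 1L, 2L), pos = c(150L, 400000L, 310000L),
    id = c("s1", "s2", "s3"), ref = "A", alt = "B"
  ))
  list(wt = wt, genes = genes, scores = scores)
}

test_that("window-gene overlap uses interval intersection", {
  fx <- ann_fixture()
  res <- genes_in_windows(fx$wt, fx$genes,
                          merged = list(A = c(1, 2), B = 3))
  sp <- res$specific
  # boundary-spanning gene is listed in both windows
  expect_equal(sort(sp$window[sp$gene == "SPAN_W1_W2"]), c(1, 2))
  expect_true("IN_W1" %in% sp$gene[sp$window == 1])
  expect_false("NOWHERE" %in% sp$gene)
  expect_equal(sp$gene[sp$breed == "B"], "IN_W3")

  # brute-force random cross-check
  set.seed(12)
  rg <- data.frame(
    chrom = as.character(sample(1:2, 40, TRUE)),
    start = sample(1e6, 40), strand = "+",
    gene = paste0("g", 1:40)
  )
  rg$end <- rg$start + sample(5e4, 40)
  res2 <- genes_in_windows(fx$wt, rg, merged = list(A = c(1, 2), B = 3))
  brute <- do.call(rbind, lapply(seq_len(nrow(fx$wt)), function(w) {
    hits <- rg$gene[
      rg$chrom == as.character(fx$wt$chrom[w]) &
        rg$start <= fx$wt$end[w] & rg$end >= fx$wt$start[w]
    ]
    if (length(hits)) data.frame(window = fx$wt$window[w], gene = hits)
  }))
  got <- res2$specific[order(res2$specific$window, res2$specific$gene),
                       c("window", "gene")]
  brute <- brute[order(brute$window, brute$gene), ]
  expect_equal(unname(as.matrix(got)), unname(as.matrix(brute)))
})

test_that("windows selected in two breeds leave the breed-specific lists", {
  fx <- ann_fixture()
  res <- genes_in_windows(fx$wt, fx$genes,
                          merged = list(A = c(1, 2), B = c(1, 3)))
  expect_false(1 %in% res$specific$window)
  expect_true(all(res$shared$window == 1))
  expect_equal(unique(res$shared$breeds), "A,B")
})

test_that("peak-snp gene screen respects the distance cutoff", {
  fx <- ann_fixture()
  pk <- peak_snp_genes(fx$wt, fx$genes, merged = list(A = c(1, 2), B = 3),
                       scores = fx$scores, near_bp = 5e4)
  # gene containing peak s1 (pos 150): IN_W1 at distance 0
  a1 <- pk[pk$window == 1 & pk$gene == "IN_W1", ]
  expect_equal(a1$distance, 0)
  # NEAR_PEAK3 is 49999 bp beyond peak s3 (pos 310000; gap to 360000)
  expect_true("NEAR_PEAK3" %in% pk$gene[pk$window == 3])
  # at near_bp + 1 it drops out
  pk2 <- peak_snp_genes(fx$wt, fx$genes, merged = list(A = c(1, 2), B = 3),
                        scores = fx$scores, near_bp = 49998)
  expect_false("NEAR_PEAK3" %in% pk2$gene[pk2$window == 3])
  expect_true(all(pk$distance <= 5e4))

  # re-running yields identical reports (pure function)
  pk3 <- peak_snp_genes(fx$wt, fx$genes, merged = list(A = c(1, 2), B = 3),
                        scores = fx$scores, near_bp = 5e4)
  expect_identical(pk, pk3)
})
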
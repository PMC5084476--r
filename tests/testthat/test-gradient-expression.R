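test_that("compute_fpkm implements the closed form and its scaling laws", {
  counts <- matrix(c(100, 0, 50, 10), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  fpkm <- compute_fpkm(counts, gene_lengths = c(g1 = 1000, g2 = 500),
                       library_sizes = c(1e6, 2e6))
  expect_equal(fpkm["g1", "s1"], 100)   # 100*1e9/(1000*1e6)
  expect_equal(fpkm["g2", "s1"], 0)
  # doubling library size halves every FPKM
  half <- compute_fpkm(counts, c(g1 = 1000, g2 = 500), c(2e6, 4e6))
  expect_equal(half, fpkm / 2)
  expect_error(compute_fpkm(counts, c(g1 = 1000, g2 = 500), c(0, 1e6)),
               class = "invalid_input")
})

test_that("filter_expressed applies the >= 1 FPKM any-sample rule", {
  m <- rbind(alllow = rep(0.5, 6),
             boundary = c(1.0, rep(0.2, 5)),
             zero = rep(0, 6))
  colnames(m) <- sprintf("sp:%d:%d", rep(1:3, each = 2), rep(1:2, 3))
  kept <- filter_expressed(m, threshold = 1)
  expect_identical(kept, "boundary")
  # brute-force oracle on a random fixture
  set.seed(10)
  big <- matrix(rlnorm(500 * 12, log(0.5), 2), 500, 12,
                dimnames = list(sprintf("g%03d", 1:500), colnames(m)[c(1:6, 1:6)]))
  brute <- rownames(big)[vapply(seq_len(nrow(big)),
                                function(i) any(big[i, ] >= 1), TRUE)]
  expect_identical(filter_expressed(big), brute)
  # threshold edge cases
  expect_setequal(filter_expressed(m, threshold = 0), rownames(m))
  expect_length(filter_expressed(m, threshold = Inf), 0)
})

test_that("segment correlations match brute-force mid-rank Spearman", {
  set.seed(11)
  # tie-laden fixture: FPKM-like data with many zeros
  m <- matrix(round(rlnorm(10 * 4, log(2), 1.5)) *
                rbinom(40, 1, 0.7), 10, 4,
              dimnames = list(NULL, sprintf("sp:%d:1", 1:4)))
  got <- segment_correlation(m, method = "spearman")
  expect_true(isSymmetric(got))
  expect_equal(unname(diag(got)), rep(1, 4))
  expect_true(all(got >= -1 & got <= 1))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(got[i, j], brute_spearman(m[, i], m[, j]), tolerance = 1e-12)
  }
  # perfect agreement / reversal
  x <- 1:10
  mm <- cbind(a = x, b = x + 5, c = rev(x))
  colnames(mm) <- sprintf("sp:%d:1", 1:3)
  corr <- segment_correlation(mm, method = "spearman")
  expect_equal(corr["sp:1:1", "sp:2:1"], 1)
  expect_equal(corr["sp:1:1", "sp:3:1"], -1)
  # constant sample emits a warning
  const <- cbind(mm[, 1:2], d = rep(3, 10))
  colnames(const) <- sprintf("sp:%d:1", 1:3)
  expect_warning(segment_correlation(const), class = "constant_sample")
})

test_that("cluster_samples reports replicate coherence and order invariance", {
  g <- generate_gradient(gradient_design(n_genes = 300, n_tf = 50,
                                         planted = NULL, seed = 21))
  x <- g$datasets$Doligosanthes
  kept <- filter_expressed(x)
  corr <- segment_correlation(x, method = "spearman", genes = kept)
  cl <- cluster_samples(corr)
  expect_true(all(cl$coherence$coherent))
  expect_equal(nrow(cl$coherence), 4)
  # identical samples merge first at distance 0
  m <- x$fpkm[kept, 1:4]
  m <- cbind(m, m[, 4])
  colnames(m) <- c(sprintf("sp:%d:1", 1:4), "sp:4:2")
  cl2 <- cluster_samples(segment_correlation(m, method = "spearman"))
  h <- cl2$tree
  first <- sort(-h$merge[1, ])
  expect_equal(h$height[1], 0, tolerance = 1e-12)
  expect_setequal(colnames(m)[first], c("sp:4:1", "sp:4:2"))
  # shuffling sample order leaves the tree topology unchanged
  perm <- c(3, 1, 4, 2, 5, 9, 6, 12, 7, 10, 8, 11)
  corr_p <- segment_correlation(x$fpkm[kept, perm])
  cl3 <- cluster_samples(corr_p)
  co <- cl$coherence[order(cl$coherence$segment), ]
  co3 <- cl3$coherence[order(cl3$coherence$segment), ]
  expect_equal(co, co3, ignore_attr = TRUE)
})

test_that("mean_profiles averages replicates and merges matched segments", {
  fpkm <- matrix(c(2, 4, 1, 1, 10, 20, 3, 5), nrow = 1)
  colnames(fpkm) <- sprintf("sp:%d:%d", rep(1:4, each = 2), rep(1:2, 4))
  rownames(fpkm) <- "g1"
  x <- structure(list(species = "sp", fpkm = fpkm,
                      segment = rep(1:4, each = 2), replicate = rep(1:2, 4)),
                 class = "gradient_dataset")
  prof <- mean_profiles(x)
  expect_equal(unname(prof["g1", ]), c(3, 1, 15, 4))  # replicate means
  # a stage matched to two native segments takes the mean of their means
  prof2 <- mean_profiles(x, match = list(c(1, 2), 2, 3, 4))
  expect_equal(unname(prof2["g1", 1]), mean(c(3, 1)))
  expect_error(mean_profiles(x, match = list(1, 2, 3, 9)),
               class = "config_error")
  expect_error(mean_profiles(x, match = list(1, 2, 3)), class = "config_error")
})
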
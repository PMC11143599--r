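test_that("region quantification caps per-base signal and masks exons", {
  plus <- list(chr1 = c(5, 1, 0, rep(1, 97)))
  cov <- make_coverage(plus)
  reg <- genomic_intervals("chr1", 0L, 3L, strand = "+")
  expect_equal(quantify_regions(cov, reg, per_position_cap = 3,
                                strand_mode = "sense"), 4)
  expect_equal(quantify_regions(cov, reg, strand_mode = "sense"), 6)
  expect_error(quantify_regions(cov, reg, per_position_cap = 0), "cap")

  body <- genomic_intervals("chr1", 0L, 100L, strand = "+")
  exon <- genomic_intervals("chr1", 0L, 50L)
  got <- quantify_regions(make_coverage(list(chr1 = rep(1, 100))), body,
                          exon_mask = exon, strand_mode = "sense")
  expect_equal(got, 50)
  # zero coverage region
  expect_equal(quantify_regions(flat_coverage(100),
                                genomic_intervals("chr1", 10L, 90L)), 0)
})

test_that("uncapped quantification equals plain interval sums", {
  set.seed(4)
  v <- list(chr1 = rpois(5000, 2))
  w <- list(chr1 = rpois(5000, 1))
  cov <- make_coverage(v, w)
  st <- sort(sample(4000, 30))
  reg <- genomic_intervals("chr1", st, st + sample(100:500, 30, TRUE))
  got <- quantify_regions(cov, reg)
  want <- vapply(seq_len(30), function(i)
    sum(v$chr1[(reg$start[i] + 1):reg$end[i]]) +
      sum(w$chr1[(reg$start[i] + 1):reg$end[i]]), 0)
  expect_equal(got, want)
})

test_that("effective-mode quantification applies the strand-balance rule", {
  v <- list(chr1 = rep(2, 100))   # plus 200
  w <- list(chr1 = c(rep(0.1, 50), rep(0, 50)))  # minus 5 -> ratio 40
  cov <- make_coverage(v, w)
  reg <- genomic_intervals("chr1", 0L, 100L)
  expect_equal(quantify_regions(cov, reg, strand_mode = "effective"), 10)
})

test_that("low-expression filter honors the min-samples rule", {
  m <- rbind(a = c(6, 7, 0), b = c(6, 0, 0), c = c(1, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  out <- filter_low_expression(m, cpm_cutoff = 5, min_samples = 2,
                               unit = "raw")
  expect_equal(rownames(out), "a")
  expect_error(filter_low_expression(m, 0.5, rpkm_cutoff = 0.5),
               "lengths")
  out2 <- filter_low_expression(m, cpm_cutoff = 5, rpkm_cutoff = 1,
                                min_samples = 2, unit = "raw",
                                feature_lengths = c(1e9, 100, 100))
  expect_equal(nrow(out2), 0L)  # huge length kills the rpkm of "a"
  # an all-zero row never survives
  m4 <- rbind(m, z = c(0, 0, 0))
  expect_false("z" %in% rownames(
    filter_low_expression(m4, 0.1, min_samples = 1, unit = "raw")))
})

test_that("RLE size factors follow the median-of-ratios definition", {
  m <- cbind(s1 = c(10, 20, 30), s2 = c(10, 20, 30))
  expect_equal(unname(rle_size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
  expect_equal(unname(rle_size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # zero-containing feature excluded from the reference
  m3 <- rbind(m2, c(0, 1000))
  expect_equal(rle_size_factors(m3), rle_size_factors(m2))
  expect_error(rle_size_factors(cbind(c(0, 1), c(1, 0))), "pseudo-reference")
})

test_that("scaling one sample scales its factor as c^(1 - 1/n)", {
  set.seed(5)
  m <- matrix(rpois(300, 50) + 1, 100, 3,
              dimnames = list(NULL, paste0("s", 1:3)))
  f1 <- rle_size_factors(m)
  c0 <- 4
  m2 <- m; m2[, 2] <- m2[, 2] * c0
  f2 <- rle_size_factors(m2)
  expect_equal(unname(f2[2] / f1[2]), c0^(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(unname(f2[1] / f1[1]), c0^(-1 / 3), tolerance = 1e-12)
})

test_that("NB QL null p-values are approximately uniform", {
  # a higher-dispersion, lower-count regime than the headline simulation
  set.seed(71)
  m <- matrix(rnbinom(2000 * 6, mu = 50, size = 5), 2000, 6)
  res <- nbql_test(m, rep(c("A", "B"), each = 3))
  expect_gt(mean(res$p_value < 0.05), 0.03)
  expect_lt(mean(res$p_value < 0.05), 0.07)
  expect_lt(unname(stats::ks.test(res$p_value, "punif")$statistic), 0.05)
})

test_that("NB QL recovers planted fold changes and handles degenerate rows", {
  set.seed(72)
  mu <- matrix(100, 600, 6); mu[1:60, 4:6] <- 400
  m <- matrix(rnbinom(600 * 6, mu = mu, size = 20), 600, 6)
  m[599, ] <- 0  # all-zero feature
  res <- nbql_test(m, rep(c("A", "B"), each = 3))
  expect_gt(mean(res$q_value[1:60] < 0.1), 0.9)
  expect_gt(median(res$log2_fold_change[1:60]), 1.5)
  expect_equal(res$p_value[599], 1)
  expect_error(nbql_test(m[, 1:4], c("A", "A", "A", "B")), ">= 2 samples")
  # a constant feature in an otherwise null matrix has log2FC ~ 0
  set.seed(79)
  m0 <- matrix(rnbinom(200 * 6, mu = 100, size = 20), 200, 6)
  m0[200, ] <- 50
  res0 <- nbql_test(m0, rep(c("A", "B"), each = 3),
                    size_factors = rep(1, 6))
  expect_equal(res0$log2_fold_change[200], 0, tolerance = 1e-6)
})

test_that("NB QL rankings agree with the reference QL implementation", {
  skip_if_not_installed("edgeR")
  set.seed(73)
  mu <- matrix(exp(runif(300, 3, 6)), 300, 6)
  mu[1:50, 4:6] <- mu[1:50, 4:6] * 3
  m <- matrix(rnbinom(300 * 6, mu = mu, size = 10), 300, 6,
              dimnames = list(sprintf("f%03d", 1:300), paste0("s", 1:6)))
  grp <- rep(c("A", "B"), each = 3)
  ours <- nbql_test(m, grp)
  y <- edgeR::DGEList(m, group = grp)
  y <- edgeR::calcNormFactors(y, method = "RLE")
  design <- model.matrix(~grp)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  ref <- edgeR::glmQLFTest(fit)$table
  expect_gt(cor(ours$p_value, ref$PValue, method = "spearman"), 0.9)
  expect_gt(cor(ours$log2_fold_change, ref$logFC), 0.98)
})

test_that("the any-change LRT detects a shifted condition", {
  set.seed(74)
  # 500 replicate features of the planted pattern (condition C 3-fold up),
  # with depth held fixed so normalization cannot absorb the shift
  mu <- matrix(rep(c(200, 200, 200, 200, 600, 600), each = 500), 500, 6)
  m <- matrix(rnbinom(500 * 6, mu = mu, size = 20), 500, 6)
  grp <- rep(c("A", "B", "C"), each = 2)
  res <- lrt_any_change(m, grp, size_factors = rep(1, 6))
  expect_gt(mean(res$q_value < 0.001), 0.8)
  # null type-I at 0.05 within a wide binomial band
  set.seed(78)
  m0 <- matrix(rnbinom(500 * 6, mu = 200, size = 20), 500, 6)
  res0 <- lrt_any_change(m0, grp, size_factors = rep(1, 6))
  t1 <- mean(res0$p_value < 0.05)
  expect_lt(abs(t1 - 0.05), 3 * sqrt(0.05 * 0.95 / 500) + 0.02)
  expect_error(lrt_any_change(m, rep("A", 6)), "conditions")
})

test_that("k-means recovers separated blocks and is seed-stable", {
  set.seed(75)
  z <- rbind(matrix(rnorm(200, 0), 50, 4), matrix(rnorm(200, 6), 50, 4))
  lab <- kmeans_profiles(z, k = 2, seed = 42)
  expect_equal(length(unique(lab[1:50])), 1L)
  expect_equal(length(unique(lab[51:100])), 1L)
  expect_false(lab[1] == lab[51])
  expect_identical(lab, kmeans_profiles(z, k = 2, seed = 42))
  expect_equal(kmeans_profiles(z, k = 1), rep(1L, 100))
  expect_error(kmeans_profiles(z, k = 0), "k must be")
  # labels renumbered by descending size
  z2 <- rbind(matrix(rnorm(40, 0), 10, 4), matrix(rnorm(360, 8), 90, 4))
  lab2 <- kmeans_profiles(z2, k = 2, seed = 1)
  expect_equal(unname(table(lab2)["1"]), 90L)
})

test_that("BH adjustment matches the closed form and the brute-force oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "p-values")
  set.seed(76)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-14)
  }
})
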
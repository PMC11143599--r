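test_that("peak matrix counts insertions and applies retention filters", {
  frags <- data.frame(chrom = "chr1", start = 100L, end = 250L,
                      barcode = "A", count = 1L)
  peaks <- genomic_intervals("chr1", c(90L, 300L, 400L), c(160L, 360L, 408L),
                             name = c("p1", "p2", "tiny"))
  pcm <- build_peak_matrix(frags, peaks, "A", min_cell_frac = -1)
  # start insertion (100) in p1; end insertion (249) outside; tiny (8 bp) gone
  expect_equal(nrow(pcm$counts), 2L)
  expect_equal(unname(pcm$counts["p1", "A"]), 1)
  expect_equal(unname(pcm$counts["p2", "A"]), 0)
  expect_error(build_peak_matrix(frags, peaks, character(0)), "barcodes")
})

test_that("peaks detected in too few cells are dropped", {
  barcodes <- sprintf("c%03d", 1:200)
  frags <- data.frame(chrom = "chr1",
                      start = c(rep(100L, 200), 500L),
                      end = c(rep(180L, 200), 580L),
                      barcode = c(barcodes, "c001"), count = 1L)
  peaks <- genomic_intervals("chr1", c(90L, 480L), c(200L, 600L),
                             name = c("common", "rare"))
  pcm <- build_peak_matrix(frags, peaks, barcodes)
  # "rare" is nonzero in 1/200 cells (0.5%) -> dropped
  expect_equal(pcm$peaks$name, "common")
})

test_that("cells proportional to the aggregate have zero raw deviation", {
  profile <- c(5, 1, 8, 2, 4, 6, 3, 7, 9, 2, 5, 4)
  X <- outer(profile, c(1, 2, 5, 10))
  pcm <- structure(list(
    peaks = genomic_intervals("chr1", seq(0, by = 100, length.out = 12),
                              seq(50, by = 100, length.out = 12),
                              name = sprintf("p%02d", 1:12)),
    barcodes = paste0("c", 1:4),
    counts = matrix(X, 12, 4, dimnames = list(sprintf("p%02d", 1:12),
                                              paste0("c", 1:4)))),
    class = "peak_cell_matrix")
  dev <- motif_deviation_scores(pcm, list(M = c(1L, 4L, 7L)), B = 10, seed = 1)
  expect_equal(unname(dev$raw["M", ]), rep(0, 4), tolerance = 1e-12)
})

test_that("raw deviations are invariant to doubling all counts", {
  truth <- shared_truth()
  fr <- shared_fragments()
  kept <- fr$labels$barcode[1:60]
  pcm <- build_peak_matrix(fr$fragments, truth$peaks, kept)
  msets <- motif_sets_from_sites(pcm, truth$motif_sites)[1:3]
  d1 <- motif_deviation_scores(pcm, msets, B = 12, seed = 4)
  pcm2 <- pcm
  pcm2$counts <- pcm2$counts * 2
  d2 <- motif_deviation_scores(pcm2, msets, B = 12, seed = 4)
  expect_equal(d1$raw, d2$raw, tolerance = 1e-12)
  # seeded determinism of the background sampling
  d3 <- motif_deviation_scores(pcm, msets, B = 12, seed = 4)
  expect_identical(d1$z, d3$z)
})

test_that("observed motif counts conserve the submatrix totals", {
  truth <- shared_truth()
  fr <- shared_fragments()
  kept <- fr$labels$barcode[1:60]
  pcm <- build_peak_matrix(fr$fragments, truth$peaks, kept)
  msets <- motif_sets_from_sites(pcm, truth$motif_sites)
  for (m in names(msets)) {
    idx <- msets[[m]]
    expect_equal(sum(colSums(pcm$counts[idx, , drop = FALSE])),
                 sum(pcm$counts[idx, ]))
  }
})

test_that("the planted motif is called for its cluster", {
  truth <- shared_truth()
  fr <- shared_fragments()
  met <- per_cell_metrics(fr$fragments, truth$peaks, truth$blacklist,
                          truth$genes)
  pcm <- build_peak_matrix(fr$fragments, truth$peaks, qc_filter(met))
  msets <- motif_sets_from_sites(pcm, truth$motif_sites)
  dev <- motif_deviation_scores(pcm, msets, seed = 7)
  cm <- cluster_specific_motifs(dev, fr$labels)
  s2 <- cm[cm$cluster == "S2", ]
  top <- s2$motif[which.max(s2$effect)]
  expect_equal(top, "M1")
  expect_true(s2$significant[s2$motif == "M1"])
  expect_error(cluster_specific_motifs(dev,
    data.frame(barcode = fr$labels$barcode, label = "one")), "clusters")
})

test_that("vectorized rank-sum p-values match wilcox.test", {
  set.seed(17)
  X <- matrix(rnorm(40 * 30), 40, 30)
  X[, 1:12] <- X[, 1:12] + rep(c(0, 1), each = 20)  # some shifted rows
  X <- round(X, 1)  # force ties
  g <- rep(c(TRUE, FALSE), c(12, 18))
  p <- groatac:::ranksum_p(groatac:::row_ranks(X), g)
  ref <- apply(X, 1, function(x)
    suppressWarnings(stats::wilcox.test(x[g], x[!g])$p.value))
  expect_equal(p, ref, tolerance = 0.02)
})

test_that("motif enrichment reproduces the 2x2 arithmetic and exact test", {
  # 20 targets (10 with a site), 100 background (10 with a site)
  mk <- function(n, prefix, offset)
    genomic_intervals("chr1", offset + seq_len(n) * 1000L,
                      offset + seq_len(n) * 1000L + 200L,
                      name = paste0(prefix, seq_len(n)))
  targets <- mk(20, "t", 0L)
  background <- mk(100, "b", 1000000L)
  sites <- rbind(
    genomic_intervals("chr1", targets$start[1:10] + 50L,
                      targets$start[1:10] + 60L, name = "MX"),
    genomic_intervals("chr1", background$start[1:10] + 50L,
                      background$start[1:10] + 60L, name = "MX"))
  res <- motif_enrichment(targets, background, sites)
  expect_equal(res$odds_ratio, 9)
  # independent hypergeometric oracle (two-sided by minimum-likelihood rule)
  dh <- stats::dhyper(0:20, 20, 100, 20)
  p_oracle <- sum(dh[dh <= dh[11] * (1 + 1e-7)])
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
})

test_that("motif enrichment degenerate cases", {
  t1 <- genomic_intervals("chr1", c(0L, 1000L), c(200L, 1200L),
                          name = c("t1", "t2"))
  b1 <- genomic_intervals("chr1", c(5000L, 7000L), c(5200L, 7200L),
                          name = c("b1", "b2"))
  # no sites anywhere: corrected OR, p = 1
  sites0 <- genomic_intervals("chr2", 1L, 10L, name = "MZ")
  res0 <- motif_enrichment(t1, b1, sites0)
  expect_equal(res0$p_value, 1)
  expect_true(is.finite(res0$odds_ratio))
  # all targets with a site, none in background: strong enrichment
  mk <- function(n, prefix, offset)
    genomic_intervals("chr1", offset + seq_len(n) * 1000L,
                      offset + seq_len(n) * 1000L + 200L,
                      name = paste0(prefix, seq_len(n)))
  targets <- mk(20, "t", 0L)
  background <- mk(100, "b", 1000000L)
  sites <- genomic_intervals("chr1", targets$start + 50L,
                             targets$start + 60L, name = "MY")
  res <- motif_enrichment(targets, background, sites)
  expect_lt(res$p_value, 1e-6)
  expect_error(motif_enrichment(t1[0, ], b1, sites0), "empty")
})
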
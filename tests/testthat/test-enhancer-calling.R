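test_that("candidates are centered peak midpoints extended by the flank", {
  cov <- flat_coverage(20000)
  peaks <- genomic_intervals("chr1", 10200L, 10800L, name = "p1")
  cand <- define_candidates(peaks, gene_models(
    genomic_intervals("chr1", 15000L, 16000L, strand = "+", name = "g")),
    cov, flank = 500L)
  expect_equal(cand$center, 10500L)
  expect_equal(cand$start, 10000L)
  expect_equal(cand$end, 11000L)
  expect_equal(cand$status, "kept")
  expect_equal(nrow(define_candidates(peaks[0, ], toy_genes(), cov)), 0L)
})

test_that("sense-transcribed gene bodies and promoters exclude candidates", {
  plus <- list(chr1 = rep(0, 20000))
  plus$chr1[2001:4000] <- 1  # sense signal on + strand gene gA [2000,4000)
  cov <- make_coverage(plus)
  genes <- toy_genes()
  # candidate overlapping gA body with sense coverage
  p1 <- genomic_intervals("chr1", 3500L, 3700L, name = "hit")
  # candidate overlapping gB body (minus strand, no minus coverage)
  p2 <- genomic_intervals("chr1", 6600L, 6800L, name = "antisense_ok")
  # candidate in gB promoter window [7500, 9000)
  p3 <- genomic_intervals("chr1", 8500L, 8700L, name = "promoter_hit")
  p4 <- genomic_intervals("chr1", 15000L, 15200L, name = "clear")
  cand <- define_candidates(rbind(p1, p2, p3, p4), genes, cov)
  expect_equal(cand$status[cand$id == "hit"], "excluded_gene_overlap")
  expect_equal(cand$status[cand$id == "antisense_ok"], "kept")
  expect_equal(cand$status[cand$id == "promoter_hit"], "excluded_gene_overlap")
  expect_equal(cand$status[cand$id == "clear"], "kept")
})

test_that("candidates beyond chromosome bounds are dropped with a warning", {
  cov <- flat_coverage(2000)
  peaks <- genomic_intervals("chr1", c(100L, 900L), c(300L, 1100L))
  expect_warning(cand <- define_candidates(peaks, toy_genes(), cov),
                 "dropped")
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$center, 1000L)
})

test_that("strand-balance rule matches its definition on fixtures", {
  cand <- make_candidates(plus = c(50, 100, 0), minus = c(40, 8, 0))
  out <- strand_balance(cand)
  expect_equal(out$balance_ratio[1], 1.25)
  expect_true(out$balanced[1])
  expect_equal(out$effective_count[1], 90)
  expect_equal(out$balance_ratio[2], 12.5)
  expect_false(out$balanced[2])
  expect_equal(out$effective_count[2], 16)
  expect_equal(out$effective_count[3], 0)
  expect_equal(out$status[3], "excluded_no_evidence")
  cand$plus_count[1] <- -1
  expect_error(strand_balance(cand), "negative")
})

test_that("raising the minor strand never lowers the effective count", {
  cand <- make_candidates(plus = 100, minus = 0)
  prev <- -Inf
  for (minor in seq(0, 120, by = 3)) {
    cand$minus_count <- minor
    eff <- strand_balance(cand)$effective_count
    expect_gte(eff, prev)
    prev <- eff
  }
})

test_that("evidence filter keeps cpm-passing or histone-backed candidates", {
  cand <- make_candidates(plus = c(0, 0, 0), minus = c(0, 0, 0),
                          id = c("a", "b", "c"),
                          effective = c(20, 500, 20))  # lib 1e5 -> cpm 200, 5000, 200
  histone <- genomic_intervals("chr1", 100L, 400L)  # overlaps only "a"
  out <- apply_evidence_filter(cand, min_cpm = 1000, library_size = 1e5,
                               histone_peaks = histone)
  expect_true(out$histone_overlap[1])
  expect_equal(out$status, c("kept", "kept", "excluded_no_evidence"))
  expect_true(out$passed_cpm[2])
  expect_error(apply_evidence_filter(cand, min_cpm = -1, library_size = 1),
               "min_cpm")
})

# independent O(n^2)-style valley scan over the same smoothed profile;
# a valley may be a flat plateau, reported at its center position
dip_oracle <- function(signal, peak, dip_threshold = 0.5, smooth_bw = 50) {
  s <- groatac:::moving_average(signal, smooth_bw)
  n <- length(s)
  hits <- list()
  for (i in seq_len(n)) {
    lo <- i; while (lo > 1 && s[lo - 1] == s[i]) lo <- lo - 1
    hi <- i; while (hi < n && s[hi + 1] == s[i]) hi <- hi + 1
    if (i != (lo + hi) %/% 2) next          # report plateau centers once
    if (lo == 1 || hi == n) next            # edge runs are not minima
    if (!(s[lo - 1] > s[i] && s[hi + 1] > s[i])) next
    summit <- min(max(s[1:i]), max(s[i:n]))
    if (summit > 0 && s[i] / summit < dip_threshold)
      hits[[length(hits) + 1]] <- c(i, s[i] / summit)
  }
  if (!length(hits)) return(data.frame(dip_center = integer(),
                                       valley_to_summit_ratio = numeric()))
  h <- do.call(rbind, hits)
  h <- h[order(h[, 2]), , drop = FALSE]
  data.frame(dip_center = as.integer(peak$start + h[, 1] - 1L),
             valley_to_summit_ratio = h[, 2])
}

test_that("dip detection finds the planted nucleosome-free valley", {
  width <- 2000L
  prof <- simulate_histone_profile(width, summit_height = 100,
                                   dip_depth = 0.25, seed = 6)
  peak <- genomic_intervals("chr1", 5000L, 5000L + width, name = "h1")
  dips <- detect_dips(prof, peak)
  expect_gte(nrow(dips), 1L)
  expect_lt(abs(dips$dip_center[1] - (5000 + width / 2)), 120)
  expect_lt(dips$valley_to_summit_ratio[1], 0.5)
})

test_that("dip detection agrees with the exhaustive valley-scan oracle", {
  set.seed(14)
  for (rep in 1:20) {
    width <- sample(500:5000, 1)
    prof <- pmax(0, stats::rnorm(width, 50, 20) +
                   50 * sin(seq(0, sample(2:8, 1) * pi, length.out = width)))
    peak <- genomic_intervals("chr1", 0L, width, name = "p")
    got <- detect_dips(prof, peak)
    want <- dip_oracle(prof, peak)
    expect_equal(got$dip_center, want$dip_center)
    expect_equal(got$valley_to_summit_ratio, want$valley_to_summit_ratio,
                 tolerance = 1e-12)
  }
})

test_that("dip detection edge cases: monotone, wide, and silent peaks", {
  peak <- genomic_intervals("chr1", 0L, 1000L, name = "p")
  expect_equal(nrow(detect_dips(seq_len(1000), peak)), 0L)
  expect_equal(nrow(detect_dips(rep(0, 1000), peak)), 0L)
  wide <- genomic_intervals("chr1", 0L, 9000L, name = "w")
  prof <- simulate_histone_profile(9000L, seed = 2)
  expect_equal(nrow(detect_dips(prof, wide)), 0L)
})

test_that("clustered candidates resolve to the best-supported member", {
  cand <- make_candidates(plus = c(0, 0), minus = c(0, 0),
                          start = c(1000L, 2300L), id = c("a", "b"),
                          effective = c(40, 90))
  atac <- genomic_intervals("chr1", 2500L, 2700L)
  out <- resolve_clusters(cand, atac_peaks = atac)
  expect_equal(out$status, c("merged_away", "kept"))
  # no overlap anywhere: maximum effective signal wins
  out2 <- resolve_clusters(cand, atac_peaks = NULL)
  expect_equal(out2$status, c("merged_away", "kept"))
  cand$effective_count <- c(90, 40)
  out3 <- resolve_clusters(cand, atac_peaks = NULL)
  expect_equal(out3$status, c("kept", "merged_away"))
  # singleton untouched
  out4 <- resolve_clusters(cand[1, , drop = FALSE], atac_peaks = NULL)
  expect_equal(out4$status, "kept")
})

test_that("dip evidence can pick the cluster representative", {
  cand <- make_candidates(plus = c(0, 0), minus = c(0, 0),
                          start = c(1000L, 2300L), id = c("a", "b"),
                          effective = c(90, 40))
  dips <- data.frame(parent_peak_id = "h", dip_center = 2800L,
                     valley_to_summit_ratio = 0.2, chrom = "chr1")
  out <- resolve_clusters(cand, dips = dips)
  expect_equal(out$status, c("merged_away", "kept"))
})

test_that("the kept set is invariant to input peak order", {
  truth <- shared_truth()
  cov <- simulate_nascent_coverage(truth, "DMSO", seed = 12)
  call1 <- call_enhancers(truth$peaks, truth$genes, cov,
                          histone_peaks = truth$histone_peaks)
  set.seed(1)
  shuf <- truth$peaks[sample(nrow(truth$peaks)), , drop = FALSE]
  call2 <- call_enhancers(shuf, truth$genes, cov,
                          histone_peaks = truth$histone_peaks)
  expect_setequal(call1$id[call1$status == "kept"],
                  call2$id[call2$status == "kept"])
})
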
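# Shared in-code fixtures for the suite.

# Coverage object from explicit per-base vectors.
make_coverage <- function(plus, minus = lapply(plus, function(v) v * 0)) {
  lens <- lapply(plus, length)
  groatac:::new_stranded_coverage(plus, minus, lens)
}

# Single-chromosome coverage of given length with optional spikes.
flat_coverage <- function(len = 10000, chrom = "chr1", value = 0) {
  make_coverage(stats::setNames(list(rep(value, len)), chrom),
                stats::setNames(list(rep(value, len)), chrom))
}

# Two-gene toy gene model set on chr1.
toy_genes <- function() {
  body <- genomic_intervals(c("chr1", "chr1"), c(2000L, 6000L),
                            c(4000L, 8000L), strand = c("+", "-"),
                            name = c("gA", "gB"))
  gene_models(body)
}

# A small default locus set + fragments shared by single-cell tests
# (built once per test run).
shared_truth <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- simulate_locus_set(seed = 11)
    val
  }
})

shared_fragments <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_fragments(shared_truth(), n_cells_per_cluster = 100,
                                 fragments_per_cell = 2000, seed = 5)
    val
  }
})

# Full-size single-cell simulation (generator defaults), memoized for the
# acceptance-scale checks.
acc_fragments <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_fragments(shared_truth(), seed = 5)
    val
  }
})

# Candidate-enhancer table fixture.
make_candidates <- function(plus, minus, chrom = "chr1",
                            start = seq(0L, by = 2000L,
                                        length.out = length(plus)),
                            id = sprintf("c%02d", seq_along(plus)),
                            effective = NULL) {
  cand <- data.frame(id = id, chrom = chrom, center = start + 500L,
                     start = start, end = start + 1000L,
                     plus_count = plus, minus_count = minus,
                     status = "kept", stringsAsFactors = FALSE)
  if (!is.null(effective)) cand$effective_count <- effective
  class(cand) <- c("candidate_enhancers", "data.frame")
  cand
}

# Brute-force step-up BH (independent oracle).
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Rank-based AUC of score separating cases (logical) from controls.
rank_auc <- function(score, case) {
  r <- rank(score)
  n1 <- sum(case); n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
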
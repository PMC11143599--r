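#' Build a peaks x cells insertion-count matrix
#'
#' Counts transposase insertion points (each fragment contributes its start
#' and `end - 1`, weighted by duplicate multiplicity) per peak per barcode.
#' Peaks narrower than `min_width` bp are discarded before counting; peaks
#' detected (nonzero) in no more than `min_cell_frac` of the kept cells are
#' dropped afterwards.
#'
#' @param fragments Fragment table.
#' @param peaks Interval table (merged peaks; a `gc` column is carried
#'   through for background matching).
#' @param kept_barcodes Barcodes to include (e.g. from [qc_filter()]).
#' @param min_width Minimum peak width in bp (default 10).
#' @param min_cell_frac Detection-fraction cutoff (default 0.01, i.e. kept
#'   if detected in > 1% of cells).
#' @return List of class `peak_cell_matrix`: `peaks` (retained peak table),
#'   `barcodes`, `counts` (peaks x cells numeric matrix).
#' @export
build_peak_matrix <- function(fragments, peaks, kept_barcodes,
                              min_width = 10L, min_cell_frac = 0.01) {
  if (length(kept_barcodes) == 0) stop("no kept barcodes")
  validate_intervals(peaks)
  peaks <- peaks[interval_width(peaks) >= min_width, , drop = FALSE]
  rownames(peaks) <- NULL
  fr <- fragments[fragments$barcode %in% kept_barcodes, , drop = FALSE]
  bc <- factor(fr$barcode, levels = kept_barcodes)
  X <- matrix(0, nrow(peaks), length(kept_barcodes),
              dimnames = list(peaks$name, kept_barcodes))
  if (nrow(fr) && nrow(peaks)) {
    ins <- genomic_intervals(rep(fr$chrom, 2),
                             c(fr$start, fr$end - 1L),
                             c(fr$start + 1L, fr$end))
    h <- interval_overlaps(ins, peaks)
    if (length(h)) {
      qi <- S4Vectors::queryHits(h)
      si <- S4Vectors::subjectHits(h)
      ci <- as.integer(bc)[(qi - 1L) %% nrow(fr) + 1L]
      wi <- rep(fr$count, 2)[qi]
      inc <- tapply(wi, list(si, ci), sum, default = 0)
      X[as.integer(rownames(inc)), as.integer(colnames(inc))] <-
        X[as.integer(rownames(inc)), as.integer(colnames(inc))] + inc
    }
  }
  detected <- rowMeans(X > 0)
  keep <- detected > min_cell_frac
  structure(list(peaks = peaks[keep, , drop = FALSE],
                 barcodes = kept_barcodes,
                 counts = X[keep, , drop = FALSE]),
            class = "peak_cell_matrix")
}

#' @export
print.peak_cell_matrix <- function(x, ...) {
  cat(sprintf("<peak_cell_matrix> %d peaks x %d cells, %.0f insertions\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Map motif sites to retained peaks
#'
#' @param pcm A `peak_cell_matrix`.
#' @param motif_sites Interval table with motif ids in `name`.
#' @return Named list: motif id -> integer indices of peaks (rows of
#'   `pcm$counts`) containing >= 1 site. Motifs hitting no retained peak are
#'   dropped.
#' @export
motif_sets_from_sites <- function(pcm, motif_sites) {
  h <- interval_overlaps(motif_sites, pcm$peaks)
  qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
  sets <- lapply(split(si, motif_sites$name[qi]), function(x) sort(unique(x)))
  sets[lengths(sets) > 0]
}

#' Per-cell motif deviation scores with matched backgrounds
#'
#' For motif m and cell c, the raw deviation is
#' `(observed - expected) / expected`, where observed is the cell's total
#' insertion count in the motif's peaks and expected assumes the cell
#' distributes its counts like the aggregate of all cells. Raw deviations
#' are standardized against `B` background peak sets, each drawn by
#' replacing every motif peak with a random peak from the same
#' (GC decile x log-mean-accessibility decile) bin, giving a z-score per
#' motif per cell. The aggregate pseudo-cell has raw deviation 0 by
#' construction.
#'
#' @param pcm A `peak_cell_matrix` (peaks need a `gc` column; constant 0.5
#'   is assumed when absent).
#' @param motifs Named list of peak-index sets (see
#'   [motif_sets_from_sites()]).
#' @param B Number of background sets (default 50, minimum 10).
#' @param gc_bins,access_bins Background-matching grid (default 10 x 10).
#' @param seed Integer seed for background sampling.
#' @return List of class `deviation_matrix`: `raw` and `z` (motifs x cells),
#'   `B`, `seed`. Cells with zero total counts get `NA` scores.
#' @export
motif_deviation_scores <- function(pcm, motifs, B = 50L, gc_bins = 10L,
                                   access_bins = 10L, seed = 1L) {
  if (B < 10) stop("B must be >= 10")
  if (!length(motifs)) stop("no motif sets")
  if (any(lengths(motifs) == 0)) stop("empty motif set")
  X <- pcm$counts
  cell_tot <- colSums(X)
  grand <- sum(X)
  peak_tot <- rowSums(X)
  gc <- if ("gc" %in% names(pcm$peaks)) pcm$peaks$gc else rep(0.5, nrow(X))
  acc <- log1p(peak_tot / ncol(X))
  ## cap the grid so bins hold ~4+ peaks; singleton bins would make the
  ## background sets degenerate (zero variance)
  k_cap <- max(1L, floor(sqrt(nrow(X) / 4)))
  gc_bins <- min(gc_bins, k_cap)
  access_bins <- min(access_bins, k_cap)
  bin_of <- function(v, k) {
    if (length(unique(v)) == 1) return(rep(1L, length(v)))
    as.integer(cut(v, breaks = unique(stats::quantile(v, seq(0, 1, length.out = k + 1))),
                   include.lowest = TRUE))
  }
  bins <- paste(bin_of(gc, gc_bins), bin_of(acc, access_bins))
  bin_members <- split(seq_len(nrow(X)), bins)
  peak_bin <- match(bins, names(bin_members))

  raw_dev <- function(idx) {
    f <- sum(peak_tot[idx]) / grand
    obs <- colSums(X[idx, , drop = FALSE])
    exp_c <- f * cell_tot
    out <- rep(NA_real_, length(cell_tot))
    ok <- exp_c > 0
    out[ok] <- (obs[ok] - exp_c[ok]) / exp_c[ok]
    out
  }

  set.seed(as.integer(seed))
  M <- length(motifs)
  raw <- matrix(NA_real_, M, ncol(X),
                dimnames = list(names(motifs), pcm$barcodes))
  z <- raw
  for (m in seq_len(M)) {
    idx <- motifs[[m]]
    r <- raw_dev(idx)
    bg <- matrix(NA_real_, B, ncol(X))
    for (b in seq_len(B)) {
      bidx <- vapply(idx, function(i) {
        mem <- bin_members[[peak_bin[i]]]
        mem[sample.int(length(mem), 1)]
      }, 0L)
      bg[b, ] <- raw_dev(bidx)
    }
    mu <- colMeans(bg)
    sdv <- apply(bg, 2, stats::sd)
    raw[m, ] <- r
    z[m, ] <- ifelse(sdv > 0, (r - mu) / sdv, NA_real_)
  }
  structure(list(raw = raw, z = z, B = as.integer(B),
                 seed = as.integer(seed)),
            class = "deviation_matrix")
}

#' @export
print.deviation_matrix <- function(x, ...) {
  cat(sprintf("<deviation_matrix> %d motifs x %d cells (B = %d)\n",
              nrow(x$z), ncol(x$z), x$B))
  invisible(x)
}

#' Cluster-specific motif activity
#'
#' For every motif and cluster, a Wilcoxon rank-sum test of z-scores in the
#' cluster versus all other cells; the effect size is the difference of mean
#' z-scores (deviation z-scores can be negative, so a literal fold change is
#' ill-defined; the threshold convention is kept). Significance requires
#' `|effect| >= lfc_threshold` and Benjamini-Hochberg `q < fdr`.
#'
#' @param dev A `deviation_matrix`.
#' @param labels Label table (`barcode`, `label`); clusters need >= 3 cells.
#' @param lfc_threshold Effect-size threshold (default 1.5).
#' @param fdr FDR threshold (default 1e-4).
#' @return `data.frame`: `motif`, `cluster`, `effect`, `p_value`, `q_value`,
#'   `significant`.
#' @export
cluster_specific_motifs <- function(dev, labels, lfc_threshold = 1.5,
                                    fdr = 1e-4) {
  lab <- labels$label[match(colnames(dev$z), labels$barcode)]
  ## drop motifs without usable scores, then cells with missing scores
  ok_motif <- rowMeans(is.na(dev$z)) < 0.5
  Z <- dev$z[ok_motif, , drop = FALSE]
  keep <- !is.na(lab) & colSums(is.na(Z)) == 0
  Z <- Z[, keep, drop = FALSE]
  lab <- lab[keep]
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  if (any(table(lab) < 3)) stop("each cluster needs >= 3 cells")
  R <- row_ranks(Z)
  tt <- row_tie_term(R)
  out <- do.call(rbind, lapply(clusters, function(cl) {
    g <- lab == cl
    p <- ranksum_p(R, g, tt)
    eff <- rowMeans(Z[, g, drop = FALSE]) - rowMeans(Z[, !g, drop = FALSE])
    data.frame(motif = rownames(Z), cluster = cl, effect = eff,
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out$q_value <- bh_fdr(out$p_value)
  out$significant <- abs(out$effect) >= lfc_threshold & out$q_value < fdr
  out
}

#' Known-motif enrichment in a region set
#'
#' Fisher's exact test on the 2x2 table of regions with/without >= 1 motif
#' site in targets versus background (background regions overlapping a
#' target are excluded). Odds ratios use the Haldane 0.5 correction when a
#' margin is zero.
#'
#' @param target_regions,background_regions Interval tables.
#' @param motif_sites Interval table with motif ids in `name`.
#' @return `data.frame`: `motif`, `odds_ratio`, `p_value`, `q_value`.
#' @export
motif_enrichment <- function(target_regions, background_regions, motif_sites) {
  if (nrow(target_regions) == 0 || nrow(background_regions) == 0)
    stop("empty target or background set")
  h <- interval_overlaps(background_regions, target_regions)
  if (length(h)) {
    background_regions <-
      background_regions[-unique(S4Vectors::queryHits(h)), , drop = FALSE]
  }
  if (nrow(background_regions) == 0)
    stop("background empty after excluding targets")
  motifs <- sort(unique(motif_sites$name))
  has_site <- function(regions, m) {
    sites <- motif_sites[motif_sites$name == m, , drop = FALSE]
    out <- rep(FALSE, nrow(regions))
    hh <- interval_overlaps(regions, sites)
    out[unique(S4Vectors::queryHits(hh))] <- TRUE
    out
  }
  res <- do.call(rbind, lapply(motifs, function(m) {
    tg <- has_site(target_regions, m)
    bg <- has_site(background_regions, m)
    a <- sum(tg); b <- sum(!tg); c <- sum(bg); d <- sum(!bg)
    p <- if (a + c == 0 || b + d == 0) 1 else
      stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    or <- if (min(a, b, c, d) == 0)
      ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) else (a * d) / (b * c)
    data.frame(motif = m, odds_ratio = or, p_value = p,
               stringsAsFactors = FALSE)
  }))
  res$q_value <- bh_fdr(res$p_value)
  res
}
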
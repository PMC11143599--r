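#' Nucleosome signal from fragment lengths
#'
#' Ratio of mononucleosome-sized fragments (lengths in `[147, 294]` bp) to
#' nucleosome-free fragments (length < 147 bp). Elevated values indicate
#' condensed, mitotic-like chromatin. With no nucleosome-free fragments the
#' ratio is `Inf` (such cells fail the QC cutoff); with no fragments at all
#' it is `NaN`.
#'
#' @param lengths Integer fragment lengths (>= 1).
#' @param counts Duplicate multiplicities (default 1).
#' @param mono_range Mononucleosome length window (default `c(147, 294)`).
#' @param free_max Nucleosome-free upper bound, exclusive (default 147).
#' @return A single non-negative number, `Inf`, or `NaN`.
#' @export
nucleosome_signal <- function(lengths, counts = rep(1L, length(lengths)),
                              mono_range = c(147L, 294L), free_max = 147L) {
  if (any(lengths < 1)) stop("fragment lengths must be >= 1")
  mono <- sum(counts[lengths >= mono_range[1] & lengths <= mono_range[2]])
  free <- sum(counts[lengths < free_max])
  if (free == 0) {
    if (mono == 0) return(NaN)
    return(Inf)
  }
  mono / free
}

## TSS positions from a gene_models object
tss_table <- function(genes) {
  data.frame(chrom = genes$body$chrom, pos = genes$body$tss,
             stringsAsFactors = FALSE)
}

#' Per-barcode fragment QC metrics
#'
#' Computes, for every cell barcode: total fragments, in-peak fragments
#' (a fragment counts if either of its two insertion points — start and
#' `end - 1` — lies in a peak), percentage of fragments in peaks, blacklist
#' ratio (fragments overlapping a blacklist region / total), nucleosome
#' signal, and TSS enrichment. TSS enrichment is the mean insertion count in
#' the central 101 bp of the TSS +/- `flank` window (aggregated over all
#' TSSs) divided by the mean insertion count in the two outermost 100 bp
#' flanks; uniform insertion coverage therefore gives 1.
#'
#' Duplicate multiplicity (the `count` column) contributes to all metrics.
#'
#' @param fragments Fragment table from [read_fragments()].
#' @param peaks Interval table of accessibility peaks.
#' @param blacklist Interval table of excluded regions (may be empty).
#' @param tss Either a `gene_models` object or a `data.frame` with `chrom`
#'   and `pos` (0-based TSS positions).
#' @param flank TSS window half-width in bp (default 2000).
#' @param ns_chrom Optional chromosome restriction for the nucleosome-signal
#'   computation (default: genome-wide).
#' @return `data.frame`, one row per barcode: `barcode`, `n_fragments`,
#'   `n_in_peaks`, `pct_reads_in_peaks`, `blacklist_ratio`,
#'   `nucleosome_signal`, `tss_enrichment`.
#' @export
per_cell_metrics <- function(fragments, peaks, blacklist = NULL, tss = NULL,
                             flank = 2000L, ns_chrom = NULL) {
  barcodes <- sort(unique(fragments$barcode))
  bc <- factor(fragments$barcode, levels = barcodes)
  w <- fragments$count
  n_frag <- as.numeric(tapply(w, bc, sum, default = 0))

  frag_iv <- genomic_intervals(fragments$chrom, fragments$start, fragments$end)

  in_peak <- rep(FALSE, nrow(fragments))
  if (!is.null(peaks) && nrow(peaks)) {
    starts <- genomic_intervals(fragments$chrom, fragments$start,
                                fragments$start + 1L)
    ends <- genomic_intervals(fragments$chrom, fragments$end - 1L,
                              fragments$end)
    in_peak[S4Vectors::queryHits(interval_overlaps(starts, peaks))] <- TRUE
    in_peak[S4Vectors::queryHits(interval_overlaps(ends, peaks))] <- TRUE
  }
  n_in_peaks <- as.numeric(tapply(w * in_peak, bc, sum, default = 0))

  in_bl <- rep(FALSE, nrow(fragments))
  if (!is.null(blacklist) && nrow(blacklist))
    in_bl[S4Vectors::queryHits(interval_overlaps(frag_iv, blacklist))] <- TRUE
  bl_ratio <- as.numeric(tapply(w * in_bl, bc, sum, default = 0)) / n_frag

  ns_sel <- if (is.null(ns_chrom)) rep(TRUE, nrow(fragments)) else
    fragments$chrom %in% ns_chrom
  len <- fragments$end - fragments$start
  mono_n <- as.numeric(tapply(w * (ns_sel & len >= 147 & len <= 294), bc,
                              sum, default = 0))
  free_n <- as.numeric(tapply(w * (ns_sel & len < 147), bc,
                              sum, default = 0))
  ns <- ifelse(free_n == 0, ifelse(mono_n == 0, NaN, Inf), mono_n / free_n)

  tssE <- rep(NA_real_, length(barcodes))
  if (!is.null(tss)) {
    if (inherits(tss, "gene_models")) tss <- tss_table(tss)
    ins <- data.frame(
      chrom = rep(fragments$chrom, 2),
      pos = c(fragments$start, fragments$end - 1L),
      bc = rep(as.integer(bc), 2),
      w = rep(w, 2))
    win <- genomic_intervals(tss$chrom, pmax(0L, tss$pos - flank),
                             tss$pos + flank + 1L)
    h <- interval_overlaps(
      genomic_intervals(ins$chrom, ins$pos, ins$pos + 1L), win)
    qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
    off <- ins$pos[qi] - (tss$pos[si] - flank)
    in_center <- abs(off - flank) <= 50
    in_flank <- off < 100 | off > 2 * flank - 100
    bci <- ins$bc[qi]; wi <- ins$w[qi]
    ctr <- tapply(wi * in_center, factor(bci, levels = seq_along(barcodes)),
                  sum, default = 0)
    flk <- tapply(wi * in_flank, factor(bci, levels = seq_along(barcodes)),
                  sum, default = 0)
    ctr <- as.numeric(ctr); flk <- as.numeric(flk)
    tssE <- ifelse(flk == 0, ifelse(ctr == 0, 0, Inf),
                   (ctr / 101) / (flk / 200))
  }

  data.frame(barcode = barcodes, n_fragments = n_frag,
             n_in_peaks = n_in_peaks,
             pct_reads_in_peaks = 100 * n_in_peaks / n_frag,
             blacklist_ratio = bl_ratio,
             nucleosome_signal = as.numeric(ns),
             tss_enrichment = tssE,
             stringsAsFactors = FALSE)
}

#' Default single-cell QC thresholds
#'
#' In-peak fragments in (1000, 100000), percent reads in peaks > 15,
#' blacklist ratio < 0.05, nucleosome signal < 10, TSS enrichment > 2.
#' All comparisons are strict.
#'
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function() {
  list(peak_fragments_min = 1000, peak_fragments_max = 1e5,
       pct_in_peaks_min = 15, blacklist_max = 0.05,
       nucleosome_signal_max = 10, tss_min = 2)
}

#' Filter cells on QC metrics
#'
#' @param metrics Output of [per_cell_metrics()].
#' @param thresholds Named list as from [qc_thresholds()]; missing entries
#'   take the defaults. Set `tss_min = -Inf` to skip a criterion.
#' @return Character vector of kept barcodes. Sentinel `Inf`/`NaN` metric
#'   values fail their criterion.
#' @export
qc_filter <- function(metrics, thresholds = qc_thresholds()) {
  th <- utils::modifyList(qc_thresholds(), thresholds)
  ok <- metrics$n_in_peaks > th$peak_fragments_min &
    metrics$n_in_peaks < th$peak_fragments_max &
    metrics$pct_reads_in_peaks > th$pct_in_peaks_min &
    metrics$blacklist_ratio < th$blacklist_max &
    metrics$nucleosome_signal < th$nucleosome_signal_max &
    metrics$tss_enrichment > th$tss_min
  ok[is.na(ok)] <- FALSE
  metrics$barcode[ok]
}

#' Per-group fragment-length histograms
#'
#' @param fragments Fragment table.
#' @param labels Label table (`barcode`, `label`); unlabeled barcodes are
#'   ignored.
#' @param max_len Maximum length tracked (default 600); longer fragments are
#'   dropped.
#' @return Integer matrix, groups x lengths `1..max_len`.
#' @export
length_histogram <- function(fragments, labels, max_len = 600L) {
  groups <- sort(unique(labels$label))
  lab <- labels$label[match(fragments$barcode, labels$barcode)]
  len <- fragments$end - fragments$start
  keep <- !is.na(lab) & len <= max_len
  out <- matrix(0L, length(groups), max_len,
                dimnames = list(groups, as.character(seq_len(max_len))))
  if (any(keep)) {
    tab <- tapply(fragments$count[keep],
                  list(factor(lab[keep], levels = groups),
                       factor(len[keep], levels = seq_len(max_len))),
                  sum, default = 0L)
    out[] <- as.integer(tab)
  }
  out
}
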
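## Sum of a per-base coverage vector over a 0-based half-open interval.
region_sum <- function(vec, start, end) {
  if (end <= start) return(0)
  sum(vec[(start + 1L):end])
}

#' Define candidate enhancer regions around peak centers
#'
#' Each accessibility peak is reduced to its midpoint and extended +/- `flank`
#' bp to a fixed-width candidate region (1 kb at the default flank of 500).
#' Candidates overlapping a gene body with nonzero sense-strand nascent
#' signal in the overlap, or overlapping any promoter, are flagged
#' `excluded_gene_overlap`: their signal is attributable to gene
#' transcription, not eRNA. Per-strand nascent counts are summed over the
#' region.
#'
#' @param peaks Interval table of candidate centers (e.g. ATAC/DHS peaks).
#' @param genes A `gene_models` object.
#' @param coverage A `stranded_coverage` object.
#' @param flank Half-width in bp (default 500).
#' @return `data.frame` of class `candidate_enhancers`: `id`, `chrom`,
#'   `center`, `start`, `end`, `plus_count`, `minus_count`, `status`.
#' @export
define_candidates <- function(peaks, genes, coverage, flank = 500L) {
  stopifnot(flank >= 1, inherits(coverage, "stranded_coverage"))
  validate_intervals(peaks)
  if (nrow(peaks) == 0)
    return(empty_candidates())
  center <- (peaks$start + peaks$end) %/% 2L
  start <- center - flank
  end <- center + flank
  lens <- unlist(coverage$chrom_lengths)[peaks$chrom]
  ok <- !is.na(lens) & start >= 0 & end <= lens
  if (any(!ok))
    warning(sum(!ok), " candidate region(s) outside chromosome bounds dropped")
  id <- if ("name" %in% names(peaks) && !anyNA(peaks$name)) peaks$name else
    sprintf("cand%04d", seq_len(nrow(peaks)))
  cand <- data.frame(id = id[ok], chrom = peaks$chrom[ok],
                     center = center[ok], start = start[ok], end = end[ok],
                     stringsAsFactors = FALSE)
  cand$plus_count <- vapply(seq_len(nrow(cand)), function(i)
    region_sum(coverage$plus[[cand$chrom[i]]], cand$start[i], cand$end[i]), 0)
  cand$minus_count <- vapply(seq_len(nrow(cand)), function(i)
    region_sum(coverage$minus[[cand$chrom[i]]], cand$start[i], cand$end[i]), 0)
  cand$status <- "kept"

  if (nrow(cand)) {
    reg <- genomic_intervals(cand$chrom, cand$start, cand$end)
    body <- genes$body
    if (nrow(body)) {
      h <- interval_overlaps(reg, body)
      if (length(h)) {
        qi <- S4Vectors::queryHits(h); si <- S4Vectors::subjectHits(h)
        sense_pos <- vapply(seq_along(qi), function(j) {
          lo <- max(cand$start[qi[j]], body$start[si[j]])
          hi <- min(cand$end[qi[j]], body$end[si[j]])
          vec <- if (body$strand[si[j]] == "+")
            coverage$plus[[body$chrom[si[j]]]] else
              coverage$minus[[body$chrom[si[j]]]]
          region_sum(vec, lo, hi) > 0
        }, NA)
        cand$status[unique(qi[sense_pos])] <- "excluded_gene_overlap"
      }
      hp <- interval_overlaps(reg, genes$promoters)
      if (length(hp))
        cand$status[unique(S4Vectors::queryHits(hp))] <- "excluded_gene_overlap"
    }
  }
  class(cand) <- c("candidate_enhancers", "data.frame")
  cand
}

empty_candidates <- function() {
  structure(data.frame(id = character(), chrom = character(),
                       center = integer(), start = integer(), end = integer(),
                       plus_count = numeric(), minus_count = numeric(),
                       status = character(), stringsAsFactors = FALSE),
            class = c("candidate_enhancers", "data.frame"))
}

#' Apply the ten-fold strand-balance rule
#'
#' Intergenic enhancers transcribe eRNA bidirectionally with approximately
#' equal strength. When the ratio of strand counts exceeds ten-fold the
#' stronger strand typically reflects read-through from an upstream gene, so
#' only the lower strand is trusted: the effective signal is symmetrized to
#' `2 x min(plus, minus)`. Balanced candidates keep `plus + minus`.
#' Candidates with zero signal on both strands are excluded.
#'
#' @param candidates Output of [define_candidates()].
#' @param max_ratio Balance-ratio cutoff (default 10).
#' @return Candidates with added `balance_ratio`, `balanced`,
#'   `effective_count`; `status` set to `excluded_no_evidence` where both
#'   strands are zero.
#' @export
strand_balance <- function(candidates, max_ratio = 10) {
  if (any(candidates$plus_count < 0) || any(candidates$minus_count < 0))
    stop("negative strand counts")
  p <- candidates$plus_count; m <- candidates$minus_count
  hi <- pmax(p, m); lo <- pmin(p, m)
  ratio <- ifelse(lo == 0, ifelse(hi == 0, NA_real_, Inf), hi / lo)
  balanced <- !is.na(ratio) & ratio <= max_ratio
  eff <- ifelse(balanced, p + m, 2 * lo)
  eff[hi == 0] <- 0
  candidates$balance_ratio <- ratio
  candidates$balanced <- balanced
  candidates$effective_count <- eff
  both_zero <- hi == 0 & candidates$status == "kept"
  candidates$status[both_zero] <- "excluded_no_evidence"
  candidates
}

#' Keep candidates with transcriptional or histone evidence
#'
#' A candidate is kept if its effective eRNA signal reaches `min_cpm`
#' counts-per-million in at least one sample, or if the region intersects at
#' least one histone-mark ChIP peak.
#'
#' @param candidates Candidates with `effective_count` (see
#'   [strand_balance()]).
#' @param min_cpm Minimum counts-per-million (default 1).
#' @param library_size Total library signal of the quantified sample;
#'   defaults to the sum of all strand counts across candidates is not
#'   meaningful, so pass the coverage total (see [call_enhancers()]).
#' @param histone_peaks Interval table of histone ChIP peaks (may be empty).
#' @param effective_matrix Optional candidates x samples matrix of effective
#'   counts with per-sample library sizes in `library_size`; the cpm test
#'   then requires >= 1 passing sample.
#' @return Candidates with logical `passed_cpm`, `histone_overlap` and
#'   updated `status`.
#' @export
apply_evidence_filter <- function(candidates, min_cpm = 1, library_size,
                                  histone_peaks = NULL,
                                  effective_matrix = NULL) {
  if (min_cpm < 0) stop("min_cpm must be >= 0")
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (is.null(effective_matrix))
    effective_matrix <- matrix(candidates$effective_count, ncol = 1)
  cpm <- sweep(effective_matrix, 2, library_size, "/") * 1e6
  candidates$passed_cpm <- apply(cpm >= min_cpm, 1, any)
  candidates$histone_overlap <- FALSE
  if (!is.null(histone_peaks) && nrow(histone_peaks) > 0 && nrow(candidates)) {
    reg <- genomic_intervals(candidates$chrom, candidates$start, candidates$end)
    h <- interval_overlaps(reg, histone_peaks)
    candidates$histone_overlap[unique(S4Vectors::queryHits(h))] <- TRUE
  }
  fail <- candidates$status == "kept" &
    !(candidates$passed_cpm | candidates$histone_overlap)
  candidates$status[fail] <- "excluded_no_evidence"
  candidates
}

## moving-average smoother with edge shrinkage
moving_average <- function(x, bw) {
  if (bw <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half <- bw %/% 2L
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

#' Detect nucleosome-free dips inside broad histone peaks
#'
#' Within a histone-mark peak (width < `max_peak_width`), a dip is a local
#' minimum of the smoothed signal whose value falls below `dip_threshold`
#' times the lower of the two flanking summits (the maxima left and right of
#' the minimum). Such dips mark nucleosome-free regions accessible to
#' transcription factors.
#'
#' @param signal Numeric per-base signal covering the peak.
#' @param peak Single-row interval table (the parent peak);
#'   `length(signal)` must equal its width.
#' @param max_peak_width Peaks at least this wide return no dips
#'   (default 7500 bp).
#' @param dip_threshold Valley-to-summit ratio cutoff (default 0.5).
#' @param smooth_bw Moving-average window in bp (default 50).
#' @return `data.frame` with `parent_peak_id`, `dip_center` (genomic
#'   coordinate), `valley_to_summit_ratio`, ordered deepest dip first.
#' @export
detect_dips <- function(signal, peak, max_peak_width = 7500L,
                        dip_threshold = 0.5, smooth_bw = 50L) {
  validate_intervals(peak)
  stopifnot(nrow(peak) == 1, length(signal) == peak$end - peak$start)
  empty <- data.frame(parent_peak_id = character(), dip_center = integer(),
                      valley_to_summit_ratio = numeric())
  if (length(signal) >= max_peak_width) return(empty)
  if (all(signal == 0)) return(empty)
  s <- moving_average(signal, smooth_bw)
  n <- length(s)
  ## plateau-aware local minima: centers of runs lower than both neighbours
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  if (k < 3) return(empty)
  is_min <- logical(k)
  for (j in 2:(k - 1))
    is_min[j] <- r$values[j] < r$values[j - 1] && r$values[j] < r$values[j + 1]
  mins <- ((starts + ends) %/% 2L)[is_min]
  if (!length(mins)) return(empty)
  ratio <- vapply(mins, function(i) {
    left <- max(s[1:i]); right <- max(s[i:n])
    summit <- min(left, right)
    if (summit <= 0) return(NA_real_)
    s[i] / summit
  }, 0)
  keep <- !is.na(ratio) & ratio < dip_threshold
  mins <- mins[keep]; ratio <- ratio[keep]
  o <- order(ratio)
  pid <- if (!is.na(peak$name[1])) peak$name[1] else "peak"
  data.frame(parent_peak_id = pid,
             dip_center = as.integer(peak$start + mins[o] - 1L),
             valley_to_summit_ratio = ratio[o],
             stringsAsFactors = FALSE)
}

#' Resolve tightly clustered candidates to one representative
#'
#' Kept candidates whose regions overlap or lie within `cluster_gap` bp form
#' a cluster. The representative is the member with the largest base-pair
#' overlap with any ATAC peak or nucleosome-free dip center (+/- 100 bp); if
#' no member overlaps either, the member with maximum effective signal wins.
#' Ties go to the smaller start coordinate. Other members are marked
#' `merged_away`.
#'
#' @param candidates Candidates with `effective_count`.
#' @param atac_peaks Interval table (may be empty/NULL).
#' @param dips Output of [detect_dips()] (may be empty/NULL).
#' @param cluster_gap Maximum gap in bp joining a cluster (default 500).
#' @return Candidates with `status` updated.
#' @export
resolve_clusters <- function(candidates, atac_peaks = NULL, dips = NULL,
                             cluster_gap = 500L) {
  keep_i <- which(candidates$status == "kept")
  if (length(keep_i) < 2) return(candidates)
  kc <- candidates[keep_i, , drop = FALSE]
  o <- order(kc$chrom, kc$start)
  kc <- kc[o, , drop = FALSE]
  keep_i <- keep_i[o]
  new_cluster <- c(TRUE, kc$chrom[-1] != kc$chrom[-nrow(kc)] |
                     kc$start[-1] - cummax_by(kc$end, kc$chrom)[-nrow(kc)] > cluster_gap)
  cl_id <- cumsum(new_cluster)

  ## evidence intervals: ATAC peaks plus dip centers +/- 100 bp
  ev <- NULL
  if (!is.null(atac_peaks) && nrow(atac_peaks))
    ev <- atac_peaks[, c("chrom", "start", "end")]
  if (!is.null(dips) && nrow(dips)) {
    if (!"chrom" %in% names(dips))
      stop("dips need a 'chrom' column for cluster resolution")
    dv <- data.frame(chrom = dips$chrom,
                     start = pmax(0L, dips$dip_center - 100L),
                     end = dips$dip_center + 101L)
    ev <- rbind(ev, dv)
  }
  ov <- if (!is.null(ev) && nrow(ev))
    max_overlap_bp(genomic_intervals(kc$chrom, kc$start, kc$end), ev)
  else numeric(nrow(kc))

  for (g in unique(cl_id)) {
    idx <- which(cl_id == g)
    if (length(idx) == 1) next
    if (any(ov[idx] > 0)) {
      best <- idx[order(-ov[idx], kc$start[idx])][1]
    } else {
      best <- idx[order(-kc$effective_count[idx], kc$start[idx])][1]
    }
    losers <- setdiff(idx, best)
    candidates$status[keep_i[losers]] <- "merged_away"
  }
  candidates
}

## running max of `end` within chrom groups (for cluster chaining)
cummax_by <- function(end, chrom) {
  out <- numeric(length(end))
  cur <- -Inf; prev <- ""
  for (i in seq_along(end)) {
    if (chrom[i] != prev) { cur <- -Inf; prev <- chrom[i] }
    cur <- max(cur, end[i])
    out[i] <- cur
  }
  out
}

#' Full eRNA-based enhancer calling
#'
#' Runs the candidate definition, strand-balance rule, evidence filter,
#' optional dip detection over histone peaks, and clustered-candidate
#' resolution in sequence.
#'
#' @param peaks Candidate-center peaks (ATAC/DHS).
#' @param genes A `gene_models` object.
#' @param coverage Strand-specific nascent coverage.
#' @param histone_peaks Histone ChIP peaks (evidence + dip parents), may be
#'   NULL.
#' @param atac_peaks ATAC peaks used for cluster resolution; defaults to
#'   `peaks`.
#' @param histone_coverage Optional unstranded per-base histone signal
#'   (list per chrom) for dip detection; when NULL dips are skipped.
#' @param flank,max_ratio,min_cpm,cluster_gap Stage parameters (see the
#'   stage functions).
#' @param library_size Library total for the cpm filter; defaults to total
#'   coverage signal.
#' @return Candidate table with all flags; kept enhancers have
#'   `status == "kept"`.
#' @export
call_enhancers <- function(peaks, genes, coverage, histone_peaks = NULL,
                           atac_peaks = peaks, histone_coverage = NULL,
                           flank = 500L, max_ratio = 10, min_cpm = 1,
                           cluster_gap = 500L, library_size = NULL) {
  if (is.null(library_size))
    library_size <- sum(vapply(coverage$plus, sum, 0)) +
      sum(vapply(coverage$minus, sum, 0))
  cand <- define_candidates(peaks, genes, coverage, flank = flank)
  cand <- strand_balance(cand, max_ratio = max_ratio)
  cand <- apply_evidence_filter(cand, min_cpm = min_cpm,
                                library_size = library_size,
                                histone_peaks = histone_peaks)
  dips <- NULL
  if (!is.null(histone_coverage) && !is.null(histone_peaks) &&
      nrow(histone_peaks)) {
    dips <- do.call(rbind, lapply(seq_len(nrow(histone_peaks)), function(i) {
      pk <- histone_peaks[i, , drop = FALSE]
      sig <- histone_coverage[[pk$chrom]][(pk$start + 1L):pk$end]
      d <- detect_dips(sig, pk)
      if (nrow(d)) d$chrom <- pk$chrom
      d
    }))
  }
  resolve_clusters(cand, atac_peaks = atac_peaks, dips = dips,
                   cluster_gap = cluster_gap)
}
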
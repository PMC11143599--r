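#' Chromatin-state-specific regions from per-cell accessibility
#'
#' Per region and state, a Wilcoxon rank-sum test of log1p-normalized
#' per-cell counts (cells in the state versus the rest) with a log2 fold
#' change of means. Significant regions (`|log2FC| >= min_fc` and BH
#' `q < fdr`) are ranked by `|log2FC|` and truncated to the `top_n` up- and
#' downregulated regions per state.
#'
#' @param x A `peak_cell_matrix` or a regions x cells count matrix.
#' @param labels Label table (`barcode`, `label`).
#' @param min_fc Minimum absolute log2 fold change (default 0.1).
#' @param fdr BH FDR threshold (default 0.1).
#' @param top_n Regions reported per direction per state (default 200).
#' @param scale_factor Per-cell normalization target (default 1e4).
#' @return List with `table` (all tests: `region`, `state`, `log2_fc`,
#'   `p_value`, `q_value`, `significant`) and `top` (per state: `up` and
#'   `down` region-id vectors).
#' @export
state_specific_regions <- function(x, labels, min_fc = 0.1, fdr = 0.1,
                                   top_n = 200L, scale_factor = 1e4) {
  X <- if (inherits(x, "peak_cell_matrix")) x$counts else as.matrix(x)
  region_ids <- if (!is.null(rownames(X))) rownames(X) else
    sprintf("region%04d", seq_len(nrow(X)))
  lab <- labels$label[match(colnames(X), labels$barcode)]
  keep <- !is.na(lab)
  X <- X[, keep, drop = FALSE]
  lab <- lab[keep]
  states <- sort(unique(lab))
  if (length(states) < 2) stop("need >= 2 states")

  tot <- colSums(X)
  tot[tot == 0] <- 1
  Xn <- log1p(sweep(X, 2, tot, "/") * scale_factor)
  R <- row_ranks(Xn)
  tt <- row_tie_term(R)
  tab <- do.call(rbind, lapply(states, function(s) {
    g <- lab == s
    p <- ranksum_p(R, g, tt)
    m1 <- rowMeans(expm1(Xn[, g, drop = FALSE]))
    m0 <- rowMeans(expm1(Xn[, !g, drop = FALSE]))
    data.frame(region = region_ids, state = s,
               log2_fc = log2((m1 + 1) / (m0 + 1)),
               p_value = p, stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  tab$q_value <- bh_fdr(tab$p_value)
  tab$significant <- abs(tab$log2_fc) >= min_fc & tab$q_value < fdr

  top <- lapply(states, function(s) {
    d <- tab[tab$state == s & tab$significant, , drop = FALSE]
    up <- d[d$log2_fc > 0, , drop = FALSE]
    dn <- d[d$log2_fc < 0, , drop = FALSE]
    list(up = utils::head(up$region[order(-abs(up$log2_fc))], top_n),
         down = utils::head(dn$region[order(-abs(dn$log2_fc))], top_n))
  })
  names(top) <- states
  list(table = tab, top = top)
}

#' Binned signal matrix around region centers
#'
#' For each center, per-base signal over `[center - flank, center + flank)`
#' is averaged within consecutive `bin_size`-bp bins, giving
#' `2 * flank / bin_size` bins per row with the region center at the
#' boundary between the two middle bins.
#'
#' @param coverage Either a named list of per-chromosome numeric vectors or
#'   a `stranded_coverage` object (strands are summed).
#' @param centers `data.frame` with `chrom` and `center`, or an interval
#'   table (midpoints are used).
#' @param flank Half-window in bp; must be divisible by `bin_size`.
#' @param bin_size Bin width in bp (default 25).
#' @return List of class `signal_matrix`: `values` (regions x bins),
#'   `bin_size`, `flank`, `region_ids`. Centers too close to a chromosome
#'   edge are dropped with a warning.
#' @export
signal_matrix <- function(coverage, centers, flank, bin_size = 25L) {
  if (flank %% bin_size != 0) stop("flank must be divisible by bin_size")
  if (inherits(coverage, "stranded_coverage")) {
    coverage <- stats::setNames(lapply(names(coverage$chrom_lengths), function(ch)
      coverage$plus[[ch]] + coverage$minus[[ch]]), names(coverage$chrom_lengths))
  }
  if (!"center" %in% names(centers)) {
    validate_intervals(centers)
    centers <- data.frame(chrom = centers$chrom,
                          center = (centers$start + centers$end) %/% 2L,
                          name = if ("name" %in% names(centers)) centers$name
                          else NA_character_,
                          stringsAsFactors = FALSE)
  }
  n_bins <- as.integer(2 * flank / bin_size)
  lens <- vapply(coverage, length, 0L)[centers$chrom]
  ok <- !is.na(lens) & centers$center - flank >= 0 & centers$center + flank <= lens
  if (any(!ok))
    warning(sum(!ok), " center(s) too close to a chromosome edge dropped")
  centers <- centers[ok, , drop = FALSE]
  vals <- matrix(0, nrow(centers), n_bins)
  for (i in seq_len(nrow(centers))) {
    v <- coverage[[centers$chrom[i]]][
      (centers$center[i] - flank + 1L):(centers$center[i] + flank)]
    vals[i, ] <- .colMeans(v, bin_size, n_bins)
  }
  ids <- if ("name" %in% names(centers) && !anyNA(centers$name))
    centers$name else sprintf("region%04d", seq_len(nrow(centers)))
  rownames(vals) <- ids
  structure(list(values = vals, bin_size = as.integer(bin_size),
                 flank = as.integer(flank), region_ids = ids),
            class = "signal_matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d regions x %d bins (%d bp bins, +/- %d bp)\n",
              nrow(x$values), ncol(x$values), x$bin_size, x$flank))
  invisible(x)
}

#' Per-group average signal profiles
#'
#' Column-wise means of a signal matrix per region group — the average
#' signal histogram companion of the heatmap.
#'
#' @param sm A `signal_matrix`.
#' @param groups Named character vector (region id -> group) or a vector
#'   aligned with the matrix rows. Groups without members are omitted with a
#'   warning.
#' @return Matrix, groups x bins.
#' @export
average_profile <- function(sm, groups) {
  if (!is.null(names(groups))) {
    g <- groups[sm$region_ids]
  } else {
    stopifnot(length(groups) == nrow(sm$values))
    g <- as.character(groups)
  }
  lev <- unique(stats::na.omit(as.character(groups)))
  out <- do.call(rbind, lapply(lev, function(gr) {
    rows <- which(!is.na(g) & g == gr)
    if (!length(rows)) return(NULL)
    colMeans(sm$values[rows, , drop = FALSE])
  }))
  present <- lev[vapply(lev, function(gr) any(!is.na(g) & g == gr), NA)]
  if (length(present) < length(lev))
    warning("empty group(s) omitted: ",
            paste(setdiff(lev, present), collapse = ", "))
  rownames(out) <- present
  out
}

#' Pseudobulk coverage per cell group
#'
#' Sums fragment-derived signal over the member cells of each group
#' (the per-state pooled track used for state-specific signal matrices).
#'
#' @param fragments Fragment table.
#' @param labels Label table (`barcode`, `label`).
#' @param chrom_lengths Named chromosome lengths.
#' @param mode `"insertion"` (start and end-1 cut sites) or `"fragment"`
#'   (the full span).
#' @return Named list: group -> list of per-chromosome numeric vectors.
#' @export
pseudobulk_coverage <- function(fragments, labels, chrom_lengths,
                                mode = c("fragment", "insertion")) {
  mode <- match.arg(mode)
  lab <- labels$label[match(fragments$barcode, labels$barcode)]
  groups <- sort(unique(stats::na.omit(lab)))
  out <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    fr <- fragments[!is.na(lab) & lab == g, , drop = FALSE]
    vecs <- lapply(chrom_lengths, function(L) numeric(L))
    for (ch in unique(fr$chrom)) {
      d <- fr[fr$chrom == ch, , drop = FALSE]
      L <- chrom_lengths[[ch]]
      if (is.null(L)) stop("unknown chromosome: ", ch)
      if (mode == "fragment") {
        delta <- numeric(L + 1L)
        s <- rowsum(as.numeric(d$count), d$start + 1L)
        delta[as.integer(rownames(s))] <- delta[as.integer(rownames(s))] + s
        e <- rowsum(as.numeric(d$count), pmin(d$end, L) + 1L)
        delta[as.integer(rownames(e))] <- delta[as.integer(rownames(e))] - e
        vecs[[ch]] <- cumsum(delta)[seq_len(L)]
      } else {
        pos <- c(d$start + 1L, pmin(d$end, L))
        w <- rep(as.numeric(d$count), 2)
        s <- rowsum(w, pos)
        v <- numeric(L)
        v[as.integer(rownames(s))] <- s
        vecs[[ch]] <- v
      }
    }
    out[[g]] <- vecs
  }
  out
}
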
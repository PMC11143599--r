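#' Quantify region-level nascent signal from base-resolution coverage
#'
#' Sums per-base signal over each region, optionally capping the per-base
#' value (mirroring a per-position read cap that suppresses PCR/alignment
#' pileups), masking exon bases (genes are quantified on intronic/exonic-free
#' bodies so that mature-RNA contamination does not inflate nascent counts),
#' and selecting strands.
#'
#' @param coverage A `stranded_coverage` object.
#' @param regions Interval table; `strand` is required for
#'   `strand_mode = "sense"`.
#' @param per_position_cap Cap applied to each base's value before summing
#'   (default NULL = no cap); must be >= 1.
#' @param exon_mask Optional interval table; bases under these intervals are
#'   excluded.
#' @param strand_mode `"both"` (plus + minus), `"sense"` (region strand), or
#'   `"effective"` (strand-balance rule: sum if within ten-fold, else
#'   `2 x min`).
#' @return Numeric vector of counts, one per region.
#' @export
quantify_regions <- function(coverage, regions, per_position_cap = NULL,
                             exon_mask = NULL,
                             strand_mode = c("both", "sense", "effective")) {
  strand_mode <- match.arg(strand_mode)
  validate_intervals(regions)
  if (!is.null(per_position_cap) && per_position_cap < 1)
    stop("per_position_cap must be >= 1")
  if (strand_mode == "sense" &&
      (!"strand" %in% names(regions) || any(!regions$strand %in% c("+", "-"))))
    stop("sense quantification needs stranded regions")
  n <- nrow(regions)
  if (n == 0) return(numeric(0))
  mask_hits <- NULL
  if (!is.null(exon_mask) && nrow(exon_mask) > 0)
    mask_hits <- interval_overlaps(regions, exon_mask)

  one_strand <- function(i, vec) {
    lo <- regions$start[i]; hi <- regions$end[i]
    v <- vec[(lo + 1L):hi]
    if (!is.null(mask_hits)) {
      mi <- S4Vectors::subjectHits(mask_hits)[S4Vectors::queryHits(mask_hits) == i]
      for (j in mi) {
        a <- max(lo, exon_mask$start[j]); b <- min(hi, exon_mask$end[j])
        if (b > a) v[(a - lo + 1L):(b - lo)] <- 0
      }
    }
    if (!is.null(per_position_cap)) v <- pmin(v, per_position_cap)
    sum(v)
  }
  vapply(seq_len(n), function(i) {
    ch <- regions$chrom[i]
    switch(strand_mode,
      both = one_strand(i, coverage$plus[[ch]]) +
        one_strand(i, coverage$minus[[ch]]),
      sense = if (regions$strand[i] == "+") one_strand(i, coverage$plus[[ch]])
        else one_strand(i, coverage$minus[[ch]]),
      effective = {
        p <- one_strand(i, coverage$plus[[ch]])
        m <- one_strand(i, coverage$minus[[ch]])
        lo <- min(p, m); hi <- max(p, m)
        if (hi == 0) 0 else if (hi / max(lo, .Machine$double.xmin) > 10)
          2 * lo else p + m
      })
  }, 0)
}

#' Counts-per-million and RPKM
#'
#' @param m Counts matrix (features x samples).
#' @param feature_lengths Feature lengths in bp (RPKM only).
#' @return Matrix of the same shape.
#' @export
cpm_matrix <- function(m) sweep(m, 2, colSums(m), "/") * 1e6

#' @rdname cpm_matrix
#' @export
rpkm_matrix <- function(m, feature_lengths) {
  if (length(feature_lengths) != nrow(m)) stop("feature_lengths mismatch")
  cpm_matrix(m) / (feature_lengths / 1000)
}

#' Filter low-expression features
#'
#' A feature is kept when its expression reaches `cpm_cutoff` in at least
#' `min_samples` samples (and, when `rpkm_cutoff` is given, also the RPKM
#' cutoff in at least `min_samples` samples). `unit = "raw"` applies the
#' cutoff to raw counts instead (the convention used for eRNA region counts).
#'
#' @param m Counts matrix.
#' @param cpm_cutoff Expression cutoff.
#' @param rpkm_cutoff Optional RPKM cutoff; requires `feature_lengths`.
#' @param min_samples Minimum qualifying samples (default 2).
#' @param feature_lengths Lengths in bp for RPKM.
#' @param unit `"cpm"` or `"raw"`.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(m, cpm_cutoff = 0.5, rpkm_cutoff = NULL,
                                  min_samples = 2L, feature_lengths = NULL,
                                  unit = c("cpm", "raw")) {
  unit <- match.arg(unit)
  if (min_samples < 1) stop("min_samples must be >= 1")
  expr <- if (unit == "cpm") cpm_matrix(m) else m
  keep <- rowSums(expr >= cpm_cutoff) >= min_samples
  if (!is.null(rpkm_cutoff)) {
    if (is.null(feature_lengths))
      stop("rpkm cutoff requested without feature lengths")
    keep <- keep &
      rowSums(rpkm_matrix(m, feature_lengths) >= rpkm_cutoff) >= min_samples
  }
  m[keep, , drop = FALSE]
}

#' Median-of-ratios (RLE) size factors
#'
#' Reference = per-feature geometric mean across samples (features with any
#' zero are excluded from the reference); each sample's factor is the median
#' ratio of its counts to the reference, rescaled so the factors have
#' geometric mean 1.
#'
#' @param m Counts matrix (features x samples).
#' @return Named positive numeric vector, one factor per sample.
#' @export
rle_size_factors <- function(m) {
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no feature with all-positive counts; consider a pseudo-reference")
  mm <- m[pos, , drop = FALSE]
  ref <- exp(rowMeans(log(mm)))
  f <- apply(mm / ref, 2, stats::median)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(m))
}

## Shared dispersion machinery: method-of-moments per-feature dispersions
## shrunk toward a lowess mean-dispersion trend, weighted by residual df.
estimate_dispersions <- function(m, group, rel_size, prior_weight = 20,
                                 floor = 1e-6) {
  q <- sweep(m, 2, rel_size, "/")
  grp <- split(seq_len(ncol(m)), group)
  G <- length(grp)
  df_resid <- ncol(m) - G
  mu <- rowMeans(q)
  if (df_resid > 0) {
    ss <- Reduce(`+`, lapply(grp, function(j) {
      gm <- rowMeans(q[, j, drop = FALSE])
      rowSums((q[, j, drop = FALSE] - gm)^2)
    }))
    s2 <- ss / df_resid
  } else s2 <- rep(0, nrow(m))
  raw <- pmax(0, (s2 - mu) / mu^2)
  raw[!is.finite(raw)] <- 0
  ok <- mu > 0
  trend <- rep(floor, nrow(m))
  if (sum(ok) >= 10) {
    ## iter = 0: robust iterations would bias the trend below the mean of the
    ## right-skewed raw dispersions
    lo <- stats::lowess(log(mu[ok]), raw[ok], f = 0.5, iter = 0)
    trend[ok] <- pmax(floor, stats::approx(lo$x, lo$y, xout = log(mu[ok]),
                                           rule = 2, ties = mean)$y)
  } else if (any(ok)) {
    trend[ok] <- pmax(floor, mean(raw[ok]))
  }
  disp <- (prior_weight * trend + df_resid * raw) / (prior_weight + df_resid)
  list(raw = raw, trend = trend, shrunk = pmax(floor, disp))
}

## One NB GLM fit at fixed dispersion; returns deviance and coefficients.
nb_fit <- function(y, X, offset, dispersion) {
  theta <- min(1e8, 1 / max(dispersion, 1e-8))
  fam <- MASS::negative.binomial(theta = theta, link = "log")
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = fam, offset = offset,
                   control = list(maxit = 50)))
  list(deviance = fit$deviance, coef = fit$coefficients)
}

#' Negative-binomial quasi-likelihood F-test for differential activity
#'
#' Fits a per-feature NB generalized log-linear model with library-size +
#' normalization offsets and empirical-Bayes-shrunk dispersions, then tests
#' a two-condition contrast with a quasi-likelihood F statistic: the
#' per-contrast deviance drop divided by a moderated quasi-dispersion
#' (residual deviance / residual df, shrunk across features). This controls
#' for dispersion-estimation uncertainty in small-sample designs.
#'
#' @param m Counts matrix (features x samples).
#' @param group Condition label per sample (character or factor).
#' @param contrast Length-2 character vector `c(numerator, denominator)`;
#'   defaults to the last vs first level.
#' @param size_factors Optional normalization factors; defaults to RLE
#'   factors (falling back to library-size factors when RLE is undefined).
#' @return `data.frame`: `feature_id`, `log2_fold_change`, `statistic` (F),
#'   `p_value`, `q_value` (Benjamini-Hochberg).
#' @export
nbql_test <- function(m, group, contrast = NULL, size_factors = NULL) {
  group <- factor(group)
  if (is.null(contrast))
    contrast <- c(levels(group)[nlevels(group)], levels(group)[1])
  if (!all(contrast %in% levels(group))) stop("unknown contrast level")
  ncontr <- table(group)[contrast]
  if (any(ncontr < 2)) stop("need >= 2 samples per contrasted condition")

  lib <- colSums(m)
  rel <- relative_size(m, lib, size_factors)
  offset <- log(rel)
  ## GLM fits use the trended dispersion; per-feature departures from the
  ## trend are absorbed by the quasi-dispersion so that numerator and
  ## denominator of the F ratio stay on the same scale
  disp <- estimate_dispersions(m, group, rel)$trend

  ## full model: one mean per condition; reduced: contrast levels merged
  X1 <- stats::model.matrix(~group)
  merged <- as.character(group)
  merged[merged == contrast[1]] <- contrast[2]
  merged <- factor(merged)
  X0 <- if (nlevels(merged) > 1) stats::model.matrix(~merged) else
    matrix(1, ncol(m), 1)
  ## contrast log-FC = coef difference between the two levels under full model
  lev <- levels(group)
  coef_of <- function(cf, level) {
    if (level == lev[1]) 0 else cf[paste0("group", level)]
  }
  n <- nrow(m)
  df1 <- 1L
  df_resid <- ncol(m) - nlevels(group)
  if (df_resid < 1) stop("no residual degrees of freedom")

  lfc <- numeric(n); Fstat <- numeric(n); phi <- rep(NA_real_, n)
  dev_drop <- numeric(n)
  nonzero <- rowSums(m) > 0
  for (i in which(nonzero)) {
    y <- m[i, ]
    f1 <- nb_fit(y, X1, offset, disp[i])
    f0 <- nb_fit(y, X0, offset, disp[i])
    dev_drop[i] <- max(0, f0$deviance - f1$deviance)
    phi[i] <- f1$deviance / df_resid
    lfc[i] <- (coef_of(f1$coef, contrast[1]) -
                 coef_of(f1$coef, contrast[2])) / log(2)
  }
  sq <- limma::squeezeVar(pmax(phi[nonzero], 1e-8), df = df_resid)
  phi_mod <- pmax(1e-6, sq$var.post)
  df_total <- df_resid + sq$df.prior
  p <- rep(1, n)
  Fstat[nonzero] <- (dev_drop[nonzero] / df1) / phi_mod
  p[nonzero] <- stats::pf(Fstat[nonzero], df1, df_total, lower.tail = FALSE)
  data.frame(
    feature_id = if (!is.null(rownames(m))) rownames(m) else
      sprintf("f%05d", seq_len(n)),
    log2_fold_change = lfc, statistic = Fstat,
    p_value = p, q_value = bh_fdr(p),
    stringsAsFactors = FALSE)
}

## normalization offsets: relative effective sizes combining library depth
## and centered RLE correction factors
relative_size <- function(m, lib, size_factors) {
  if (is.null(size_factors)) {
    size_factors <- tryCatch(rle_size_factors(m), error = function(e) {
      f <- lib / exp(mean(log(lib)))
      f
    })
  }
  sf <- size_factors / exp(mean(log(size_factors)))
  sf
}

#' Any-change likelihood ratio test across conditions
#'
#' NB GLM with one mean per condition versus intercept-only, an
#' ANOVA-like test for a change between any pair of conditions. The LRT
#' statistic is referred to a chi-square with `levels - 1` df.
#'
#' @inheritParams nbql_test
#' @return `data.frame` as for [nbql_test()]; `log2_fold_change` is the
#'   largest pairwise log2 difference of fitted condition means.
#' @export
lrt_any_change <- function(m, group, size_factors = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need >= 2 conditions")
  lib <- colSums(m)
  rel <- relative_size(m, lib, size_factors)
  offset <- log(rel)
  disp <- estimate_dispersions(m, group, rel)$shrunk
  X1 <- stats::model.matrix(~group)
  X0 <- matrix(1, ncol(m), 1)
  df1 <- nlevels(group) - 1L
  n <- nrow(m)
  stat <- numeric(n); lfc <- numeric(n)
  p <- rep(1, n)
  for (i in which(rowSums(m) > 0)) {
    y <- m[i, ]
    f1 <- nb_fit(y, X1, offset, disp[i])
    f0 <- nb_fit(y, X0, offset, disp[i])
    stat[i] <- max(0, f0$deviance - f1$deviance)
    cf <- c(0, f1$coef[-1])
    lfc[i] <- (max(cf) - min(cf)) / log(2)
    p[i] <- stats::pchisq(stat[i], df = df1, lower.tail = FALSE)
  }
  data.frame(
    feature_id = if (!is.null(rownames(m))) rownames(m) else
      sprintf("f%05d", seq_len(n)),
    log2_fold_change = lfc, statistic = stat,
    p_value = p, q_value = bh_fdr(p),
    stringsAsFactors = FALSE)
}

#' K-means clustering of standardized expression profiles
#'
#' K-means with k-means++ seeding, 25 restarts under a fixed seed; cluster
#' labels are renumbered by descending cluster size so label 1 is always the
#' largest cluster.
#'
#' @param z Features x conditions matrix (typically row-standardized).
#' @param k Number of clusters (default 6).
#' @param seed Integer seed.
#' @param restarts Number of restarts (default 25).
#' @return Integer vector of cluster labels (1..k).
#' @export
kmeans_profiles <- function(z, k = 6L, seed = 1L, restarts = 25L) {
  if (k < 1) stop("k must be >= 1")
  z <- as.matrix(z)
  if (k > nrow(z)) stop("k exceeds number of features")
  if (k == 1) return(rep(1L, nrow(z)))
  set.seed(as.integer(seed))
  best <- NULL
  for (r in seq_len(restarts)) {
    ctr <- kmeanspp_centers(z, k)
    fit <- suppressWarnings(stats::kmeans(z, centers = ctr, iter.max = 100))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  sizes <- tabulate(best$cluster, nbins = k)
  relabel <- order(order(-sizes, seq_len(k)))
  relabel[best$cluster]
}

kmeanspp_centers <- function(z, k) {
  n <- nrow(z)
  idx <- sample.int(n, 1)
  for (j in 2:k) {
    d2 <- apply(z, 1, function(row)
      min(colSums((t(z[idx, , drop = FALSE]) - row)^2)))
    d2[idx] <- 0
    if (sum(d2) == 0) idx <- c(idx, sample(setdiff(seq_len(n), idx), 1))
    else idx <- c(idx, sample.int(n, 1, prob = d2))
  }
  z[idx, , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' Standard step-up FDR adjustment, order-preserving against the input.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return q-values of the same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
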
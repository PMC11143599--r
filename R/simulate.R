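#' Simulate a toy genome with planted regulatory elements
#'
#' Places genes, intergenic enhancers, accessibility peaks (true + decoy),
#' broad histone peaks and blacklist regions on a small genome, and plants the
#' ground truth the downstream modules are validated against: per-condition
#' eRNA and gene transcription rates, strand-balance class, motif-to-peak
#' assignments and per-cell-cluster phenotypes (mononucleosome fraction,
#' motif-activity multiplier, state-specific accessible peaks).
#'
#' Each chromosome is divided into equal slots, one feature per slot, which
#' guarantees genes and enhancers never overlap and enhancers stay >= 2 kb
#' from any gene.
#'
#' @param seed Integer seed; identical seeds give identical output.
#' @param n_chroms,chrom_length Genome shape (default 2 x 2 Mb).
#' @param n_genes,n_enhancers,n_decoys Feature counts (defaults 60/120/80).
#' @param imbalanced_frac Fraction of enhancers transcribed with a >= 92/8
#'   strand split (default 0.1); the rest are balanced (~50/50).
#' @param conditions Condition labels (default DMSO vs treated).
#' @param diff_frac Fraction of genes and enhancers with a planted fold
#'   change in the second condition.
#' @param histone_frac Fraction of enhancers covered by a broad histone peak.
#' @param n_motifs Number of motifs; motif `M1` is the planted
#'   differentially active motif (cluster `S2`).
#' @param n_clusters Number of cell clusters/chromatin states.
#' @param n_state_peaks Planted state-specific accessible peaks per cluster.
#' @return A list of class `synthetic_truth`; see Details in the package
#'   vignette. Key elements: `chrom_lengths`, `genes` (gene_models),
#'   `enhancers`, `peaks` (with `gc` and `is_decoy`), `histone_peaks`,
#'   `blacklist`, `motif_sites`, `motif_assignments`, `clusters`,
#'   `state_peaks`, `conditions`.
#' @export
simulate_locus_set <- function(seed = 1L,
                               n_chroms = 2L, chrom_length = 2e6,
                               n_genes = 60L, n_enhancers = 120L,
                               n_decoys = 80L,
                               imbalanced_frac = 0.1,
                               conditions = c("DMSO", "AZD1775"),
                               diff_frac = 0.3,
                               histone_frac = 0.6,
                               n_motifs = 8L, n_clusters = 3L,
                               n_state_peaks = 20L) {
  set.seed(as.integer(seed))
  n_feat <- n_genes + n_enhancers + n_decoys
  per_chrom <- rep(n_feat %/% n_chroms, n_chroms)
  if (n_feat %% n_chroms) per_chrom[seq_len(n_feat %% n_chroms)] <-
      per_chrom[seq_len(n_feat %% n_chroms)] + 1L
  slot_w <- floor(chrom_length / max(per_chrom))
  if (slot_w < 15000)
    stop("infeasible packing: chromosome too small for requested feature count")
  chroms <- paste0("chr", seq_len(n_chroms))
  chrom_lengths <- stats::setNames(as.list(rep(as.integer(chrom_length), n_chroms)), chroms)

  kind <- sample(rep(c("gene", "enhancer", "decoy"),
                     c(n_genes, n_enhancers, n_decoys)))
  chrom <- rep(chroms, per_chrom)
  slot_idx <- unlist(lapply(per_chrom, seq_len))
  centers <- as.integer((slot_idx - 0.5) * slot_w +
                          round(stats::runif(n_feat, -slot_w / 8, slot_w / 8)))

  ## genes: stranded bodies with exon structure and per-condition rates
  gi <- which(kind == "gene")
  gene_w <- as.integer(round(stats::runif(n_genes, 4000, 10000)))
  gb <- genomic_intervals(chrom[gi],
                          centers[gi] - gene_w %/% 2L,
                          centers[gi] - gene_w %/% 2L + gene_w,
                          strand = sample(c("+", "-"), n_genes, replace = TRUE),
                          name = sprintf("gene%03d", seq_len(n_genes)))
  exon_list <- lapply(seq_len(n_genes), function(i) {
    n_ex <- sample(2:4, 1)
    bnd <- sort(sample(seq(200L, gene_w[i] - 200L, by = 50L), 2L * n_ex))
    data.frame(chrom = gb$chrom[i],
               start = gb$start[i] + bnd[seq(1, 2 * n_ex, 2)],
               end = gb$start[i] + bnd[seq(2, 2 * n_ex, 2)],
               strand = gb$strand[i], name = gb$name[i], score = NA_real_)
  })
  genes <- gene_models(gb, do.call(rbind, exon_list))
  gene_rate <- stats::rgamma(n_genes, shape = 4, scale = 0.005)  # per-base sense rate
  gene_diff <- stats::runif(n_genes) < diff_frac
  gene_lfc <- ifelse(gene_diff, sample(c(-1, 1), n_genes, TRUE) *
                       stats::runif(n_genes, 1, 2), 0)
  gene_tab <- data.frame(name = gb$name, rate = gene_rate,
                         lfc = gene_lfc, stringsAsFactors = FALSE)

  ## enhancers: intergenic eRNA sources
  ei <- which(kind == "enhancer")
  balanced <- stats::runif(n_enhancers) >= imbalanced_frac
  enh_rate <- stats::rgamma(n_enhancers, shape = 9, scale = 300 / 9)  # total counts/region
  enh_diff <- stats::runif(n_enhancers) < diff_frac
  enh_lfc <- ifelse(enh_diff, sample(c(-1, 1), n_enhancers, TRUE) *
                      stats::runif(n_enhancers, 1, 2), 0)
  plus_frac <- ifelse(balanced, stats::runif(n_enhancers, 0.45, 0.55),
                      ifelse(stats::runif(n_enhancers) < 0.5, 0.95, 0.05))
  enhancers <- data.frame(
    id = sprintf("enh%03d", seq_len(n_enhancers)),
    chrom = chrom[ei], center = centers[ei],
    rate = enh_rate, lfc = enh_lfc, balanced = balanced,
    plus_frac = plus_frac, stringsAsFactors = FALSE)

  ## accessibility peaks: one per enhancer + decoys
  di <- which(kind == "decoy")
  peak_w <- as.integer(round(stats::runif(n_enhancers + n_decoys, 300, 600)))
  peak_center <- c(centers[ei], centers[di])
  peak_chrom <- c(chrom[ei], chrom[di])
  peaks <- genomic_intervals(peak_chrom,
                             peak_center - peak_w %/% 2L,
                             peak_center - peak_w %/% 2L + peak_w,
                             name = sprintf("peak%03d", seq_len(n_enhancers + n_decoys)))
  peaks$gc <- round(stats::runif(nrow(peaks), 0.3, 0.7), 3)
  peaks$is_decoy <- rep(c(FALSE, TRUE), c(n_enhancers, n_decoys))
  peaks$enhancer_id <- c(enhancers$id, rep(NA_character_, n_decoys))

  ## broad histone peaks (1-7 kb) over a subset of enhancers
  hi <- which(stats::runif(n_enhancers) < histone_frac)
  hw <- as.integer(round(stats::runif(length(hi), 1000, 7000)))
  histone_peaks <- genomic_intervals(
    enhancers$chrom[hi],
    pmax(0L, enhancers$center[hi] - hw %/% 2L),
    enhancers$center[hi] - hw %/% 2L + hw,
    name = sprintf("hpeak%03d", seq_along(hi)))
  histone_peaks$enhancer_id <- enhancers$id[hi]

  ## blacklist on a subset of decoys
  bl <- utils::head(which(peaks$is_decoy), round(0.12 * n_decoys))
  blacklist <- peaks[bl, c("chrom", "start", "end")]
  blacklist$strand <- "*"
  blacklist$name <- sprintf("bl%02d", seq_len(nrow(blacklist)))
  blacklist$score <- NA_real_
  rownames(blacklist) <- NULL

  ## motifs: M1 is the planted cluster-specific motif
  motif_ids <- sprintf("M%d", seq_len(n_motifs))
  motif_assignments <- lapply(motif_ids, function(m)
    sort(sample(nrow(peaks), max(3L, round(0.15 * nrow(peaks))))))
  names(motif_assignments) <- motif_ids
  motif_sites <- do.call(rbind, lapply(motif_ids, function(m) {
    idx <- motif_assignments[[m]]
    ctr <- (peaks$start[idx] + peaks$end[idx]) %/% 2L
    data.frame(chrom = peaks$chrom[idx], start = ctr - 10L, end = ctr + 10L,
               strand = "*", name = m, score = NA_real_)
  }))
  rownames(motif_sites) <- NULL

  ## cell clusters: S3 models the condensed mitotic-like state;
  ## S2 carries the planted M1 motif activity
  cl_names <- sprintf("S%d", seq_len(n_clusters))
  mono <- rep(0.3, n_clusters)
  if (n_clusters >= 3) mono[n_clusters] <- 0.8
  motif_mult <- rep(1, n_clusters)
  if (n_clusters >= 2) motif_mult[2] <- 2
  clusters <- data.frame(cluster = cl_names, mono_frac = mono,
                         motif_multiplier = motif_mult,
                         stringsAsFactors = FALSE)
  ## state-specific accessible peaks (non-decoy, disjoint across states)
  avail <- sample(which(!peaks$is_decoy))
  state_peaks <- stats::setNames(vector("list", n_clusters), cl_names)
  for (i in seq_len(n_clusters)) {
    take <- utils::head(avail, n_state_peaks)
    avail <- setdiff(avail, take)
    state_peaks[[i]] <- sort(take)
  }

  structure(list(
    seed = as.integer(seed), chrom_lengths = chrom_lengths,
    genes = genes, gene_truth = gene_tab,
    enhancers = enhancers, peaks = peaks,
    histone_peaks = histone_peaks, blacklist = blacklist,
    motif_sites = motif_sites, motif_assignments = motif_assignments,
    clusters = clusters, state_peaks = state_peaks,
    state_access_fc = 3, conditions = conditions,
    background_rate = 1e-5, enh_window = 300L
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_truth> %d chroms, %d genes, %d enhancers ",
                     "(%d balanced), %d peaks (%d decoys), %d motifs\n"),
              length(x$chrom_lengths), nrow(x$genes$body),
              nrow(x$enhancers), sum(x$enhancers$balanced),
              nrow(x$peaks), sum(x$peaks$is_decoy),
              length(x$motif_assignments)))
  invisible(x)
}

#' Simulate strand-specific nascent coverage for one sample
#'
#' Per-base counts are Poisson with rate = uniform background + gene
#' sense-strand rate over gene bodies + enhancer eRNA rate spread over a
#' +/- 300 bp window around the enhancer center and split across strands
#' (balanced enhancers ~50/50, imbalanced >= 92/8). Region-level biological
#' dispersion is added by Gamma-mixing each feature's rate per sample
#' (negative-binomial counts at the region level).
#'
#' @param truth A `synthetic_truth` object.
#' @param condition One of `truth$conditions`; planted fold changes apply to
#'   the second condition onward.
#' @param depth Depth multiplier (>= 0).
#' @param seed Integer seed.
#' @param dispersion Gamma-mixing dispersion (default 0.1); 0 = pure Poisson.
#' @return A `stranded_coverage` object.
#' @export
simulate_nascent_coverage <- function(truth, condition, depth = 1, seed = 1L,
                                      dispersion = 0.1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!condition %in% truth$conditions)
    stop("unknown condition: ", condition)
  if (depth < 0) stop("negative depth")
  set.seed(as.integer(seed))
  treated <- match(condition, truth$conditions) > 1
  gmix <- function(n) if (dispersion > 0)
    stats::rgamma(n, shape = 1 / dispersion, scale = dispersion) else rep(1, n)

  rate_p <- lapply(truth$chrom_lengths, function(L) rep(truth$background_rate, L))
  rate_m <- lapply(truth$chrom_lengths, function(L) rep(truth$background_rate, L))

  gb <- truth$genes$body
  gmult <- gmix(nrow(gb)) * ifelse(rep(treated, nrow(gb)),
                                   2^truth$gene_truth$lfc, 1)
  for (i in seq_len(nrow(gb))) {
    idx <- (gb$start[i] + 1L):gb$end[i]
    r <- truth$gene_truth$rate[i] * gmult[i]
    if (gb$strand[i] == "+") {
      rate_p[[gb$chrom[i]]][idx] <- rate_p[[gb$chrom[i]]][idx] + r
    } else {
      rate_m[[gb$chrom[i]]][idx] <- rate_m[[gb$chrom[i]]][idx] + r
    }
  }

  en <- truth$enhancers
  W <- truth$enh_window
  emult <- gmix(nrow(en)) * ifelse(rep(treated, nrow(en)), 2^en$lfc, 1)
  for (i in seq_len(nrow(en))) {
    L <- truth$chrom_lengths[[en$chrom[i]]]
    lo <- max(0L, en$center[i] - W)
    hi <- min(L, en$center[i] + W)
    idx <- (lo + 1L):hi
    per_base <- en$rate[i] * emult[i] / (2 * W)
    rate_p[[en$chrom[i]]][idx] <- rate_p[[en$chrom[i]]][idx] +
      per_base * en$plus_frac[i]
    rate_m[[en$chrom[i]]][idx] <- rate_m[[en$chrom[i]]][idx] +
      per_base * (1 - en$plus_frac[i])
  }

  plus <- lapply(rate_p, function(v) as.numeric(stats::rpois(length(v), v * depth)))
  minus <- lapply(rate_m, function(v) as.numeric(stats::rpois(length(v), v * depth)))
  new_stranded_coverage(plus, minus, truth$chrom_lengths)
}

#' Simulate a single-cell fragments table with planted cell phenotypes
#'
#' Fragment midpoints concentrate in accessibility peaks; peak choice within
#' a cell is weighted by the cluster's planted state-specific accessibility
#' and by the cluster's motif-activity multiplier on motif-M1 peaks.
#' Fragment lengths follow a two-component mixture: sub-nucleosomal
#' (mean 75 bp, < 147) and mononucleosomal (mean 200 bp, in [147, 294]),
#' mixed per cell by the cluster's mononucleosome fraction.
#'
#' @param truth A `synthetic_truth` object.
#' @param n_cells_per_cluster Cells per cluster (default 200).
#' @param fragments_per_cell Fragments per cell (default 2000).
#' @param seed Integer seed.
#' @param in_peak_frac Fraction of fragments placed in peaks (default 0.65).
#' @param tss_frac Fraction of fragments placed at gene TSSs (default 0.15),
#'   emulating promoter accessibility; the remainder is uniform background.
#' @return List with `fragments` (chrom/start/end/barcode/count, sorted by
#'   position) and `labels` (barcode, label).
#' @export
simulate_fragments <- function(truth, n_cells_per_cluster = 200L,
                               fragments_per_cell = 2000L, seed = 1L,
                               in_peak_frac = 0.65, tss_frac = 0.15) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (fragments_per_cell < 1) stop("fragments_per_cell must be >= 1")
  if (n_cells_per_cluster < 1) stop("need >= 1 cell per cluster")
  set.seed(as.integer(seed))
  cl <- truth$clusters
  n_cl <- nrow(cl)
  barcodes <- sprintf("%s_c%03d", rep(cl$cluster, each = n_cells_per_cluster),
                      rep(seq_len(n_cells_per_cluster), n_cl))
  cell_cluster <- rep(seq_len(n_cl), each = n_cells_per_cluster)
  n_cells <- length(barcodes)
  N <- n_cells * fragments_per_cell
  frag_cell <- rep(seq_len(n_cells), each = fragments_per_cell)

  ## lengths: per-cell mononucleosome mixture
  mono_frac <- cl$mono_frac[cell_cluster][frag_cell]
  is_mono <- stats::runif(N) < mono_frac
  len <- integer(N)
  len[is_mono] <- pmin(294L, pmax(147L, as.integer(round(
    stats::rnorm(sum(is_mono), 200, 25)))))
  len[!is_mono] <- pmin(146L, pmax(20L, as.integer(round(
    stats::rnorm(sum(!is_mono), 75, 25)))))

  ## midpoints: in-peak (cluster-weighted peak choice) vs uniform background
  pk <- truth$peaks
  pk_center <- (pk$start + pk$end) %/% 2L
  pk_halfw <- (pk$end - pk$start) %/% 2L
  m1 <- truth$motif_assignments[["M1"]]
  u <- stats::runif(N)
  in_peak <- u < in_peak_frac
  at_tss <- !in_peak & u < in_peak_frac + tss_frac
  chrom_ids <- names(truth$chrom_lengths)
  chrom <- character(N)
  mid <- integer(N)
  ## background fragments: uniform over the genome
  is_bg <- !in_peak & !at_tss
  bgn <- sum(is_bg)
  bg_ch <- sample(length(chrom_ids), bgn, replace = TRUE)
  chrom[is_bg] <- chrom_ids[bg_ch]
  mid[is_bg] <- as.integer(stats::runif(bgn, 200,
                                        unlist(truth$chrom_lengths)[bg_ch] - 200))
  ## promoter fragments: tight around gene TSSs
  tssn <- sum(at_tss)
  gi <- sample.int(nrow(truth$genes$body), tssn, replace = TRUE)
  chrom[at_tss] <- truth$genes$body$chrom[gi]
  mid[at_tss] <- truth$genes$body$tss[gi] +
    as.integer(round(stats::rnorm(tssn, 0, 50)))
  ## in-peak fragments, per cluster (weights shared within a cluster)
  for (k in seq_len(n_cl)) {
    w <- rep(1, nrow(pk))
    sp <- truth$state_peaks[[cl$cluster[k]]]
    if (length(sp)) w[sp] <- w[sp] * truth$state_access_fc
    if (!is.null(m1)) w[m1] <- w[m1] * cl$motif_multiplier[k]
    sel <- which(in_peak & cell_cluster[frag_cell] == k)
    pidx <- sample.int(nrow(pk), length(sel), replace = TRUE, prob = w)
    off <- as.integer(round(stats::rnorm(length(sel), 0, pk_halfw[pidx] / 2)))
    off <- pmax(-pk_halfw[pidx], pmin(pk_halfw[pidx], off))
    chrom[sel] <- pk$chrom[pidx]
    mid[sel] <- pk_center[pidx] + off
  }
  start <- pmax(0L, mid - len %/% 2L)
  frags <- data.frame(chrom = chrom, start = start, end = start + len,
                      barcode = barcodes[frag_cell], count = 1L,
                      stringsAsFactors = FALSE)
  o <- order(frags$chrom, frags$start, frags$end, frags$barcode)
  frags <- frags[o, , drop = FALSE]
  rownames(frags) <- NULL
  labels <- data.frame(barcode = barcodes,
                       label = cl$cluster[cell_cluster],
                       stringsAsFactors = FALSE)
  list(fragments = frags, labels = labels)
}

#' Simulate base-level histone ChIP signal over a broad peak
#'
#' Produces a bimodal profile with a central nucleosome-free dip at the
#' parent enhancer center, used to exercise dip detection.
#'
#' @param width Peak width in bp.
#' @param summit_height Mean summit signal.
#' @param dip_depth Valley level as a fraction of the summit (default 0.25).
#' @param seed Integer seed.
#' @return Numeric vector of length `width`.
#' @export
simulate_histone_profile <- function(width, summit_height = 100,
                                     dip_depth = 0.25, seed = 1L) {
  set.seed(as.integer(seed))
  x <- seq_len(width)
  c0 <- width / 2
  s <- width / 6
  base <- exp(-((x - c0)^2) / (2 * s^2))
  dip <- 1 - (1 - dip_depth) * exp(-((x - c0)^2) / (2 * (width / 20)^2))
  mu <- summit_height * base * dip
  as.numeric(stats::rpois(width, mu))
}

#' Write all generated inputs of a synthetic locus set to disk
#'
#' Emits the external-file forms of a simulated study: peak/histone/
#' blacklist/motif-site BEDs, a BED6+ gene table with exons, and a JSON
#' ground-truth summary.
#'
#' @param truth A `synthetic_truth` object.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_locus_set <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  pk <- truth$peaks
  pk$score <- as.numeric(!pk$is_decoy)
  write_bed(pk, p("atac_peaks.bed"))
  write_bed(truth$histone_peaks, p("histone_peaks.bed"))
  write_bed(truth$blacklist, p("blacklist.bed"))
  write_bed(truth$motif_sites, p("motif_sites.bed"))
  gb <- truth$genes$body
  utils::write.table(
    data.frame(gb$chrom, gb$start, gb$end, gb$name, 0, gb$strand, gb$tss),
    p("genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  write_bed(truth$genes$exons, p("exons.bed"))
  jsonlite::write_json(list(
    seed = truth$seed,
    chrom_lengths = truth$chrom_lengths,
    enhancers = truth$enhancers,
    gene_truth = truth$gene_truth,
    clusters = truth$clusters,
    conditions = truth$conditions
  ), p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(peaks = p("atac_peaks.bed"),
                 histone = p("histone_peaks.bed"),
                 blacklist = p("blacklist.bed"),
                 motif_sites = p("motif_sites.bed"),
                 genes = p("genes.tsv"), exons = p("exons.bed"),
                 truth = p("truth.json")))
}

#' Read a BED6+ gene table (as written by [write_locus_set()])
#'
#' @param path Gene table path (chrom, start, end, name, score, strand).
#' @param exon_path Optional exon BED with gene names in column 4.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(path, exon_path = NULL) {
  g <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  body <- genomic_intervals(g[[1]], g[[2]], g[[3]], strand = g[[6]],
                            name = g[[4]])
  exons <- if (!is.null(exon_path)) read_bed(exon_path) else NULL
  if (!is.null(exons) && nrow(exons)) {
    exons$strand <- body$strand[match(exons$name, body$name)]
  }
  gene_models(body, exons)
}
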
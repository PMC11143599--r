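default_config <- function() {
  list(
    seed = 1L,
    log = "info",
    simulate = list(
      enabled = TRUE,
      n_chroms = 2L, chrom_length = 2e6,
      n_genes = 60L, n_enhancers = 120L, n_decoys = 80L,
      n_replicates = 3L, depth = 1,
      n_cells_per_cluster = 200L, fragments_per_cell = 2000L
    ),
    inputs = list(
      peaks = "", genes = "", exons = "", plus_bedgraph = "",
      minus_bedgraph = "", fragments = "", labels = "", histone = "",
      blacklist = "", motif_sites = ""
    ),
    enhancers = list(flank = 500L, max_ratio = 10, min_cpm = 1,
                     cluster_gap = 500L),
    quantify = list(per_position_cap = 3L),
    diff = list(count_cutoff = 5, min_samples = 2L, fdr = 0.1,
                lrt_fdr = 0.001, kmeans_k = 6L),
    fragqc = list(tss_flank = 2000L),
    motifs = list(B = 50L, lfc_threshold = 1.5, fdr = 1e-4),
    aggregate = list(flank = 1000L, bin_size = 25L, min_fc = 0.1,
                     fdr = 0.1, top_n = 200L)
  )
}

check_section <- function(value, default, path, errors) {
  for (key in names(value)) {
    kp <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(default)) {
      errors <- c(errors, sprintf("unknown key: %s", kp))
      next
    }
    d <- default[[key]]
    v <- value[[key]]
    if (is.list(d)) {
      if (!is.list(v)) {
        errors <- c(errors, sprintf("key %s: expected a section", kp))
      } else {
        errors <- check_section(v, d, kp, errors)
      }
    } else if (is.numeric(d) && !is.numeric(v)) {
      errors <- c(errors, sprintf("key %s: expected a number, got %s",
                                  kp, class(v)[1]))
    } else if (is.character(d) && !is.character(v)) {
      errors <- c(errors, sprintf("key %s: expected a string, got %s",
                                  kp, class(v)[1]))
    } else if (is.logical(d) && !is.logical(v)) {
      errors <- c(errors, sprintf("key %s: expected true/false, got %s",
                                  kp, class(v)[1]))
    }
  }
  errors
}

merge_config <- function(value, default) {
  for (key in names(value)) {
    if (is.list(default[[key]])) {
      default[[key]] <- merge_config(value[[key]], default[[key]])
    } else {
      default[[key]] <- value[[key]]
    }
  }
  default
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML config, rejects unknown keys and type mismatches (all
#' problems are reported at once), and injects defaults for everything else.
#' An empty file yields the all-defaults configuration.
#'
#' @param path YAML file path, or a list already in config shape.
#' @return Normalized configuration list.
#' @export
validate_config <- function(path) {
  raw <- if (is.list(path)) path else {
    if (!file.exists(path)) stop("config file not found: ", path)
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  errors <- check_section(raw, default_config(), "", character())
  if (length(errors))
    stop("invalid configuration:\n  ", paste(errors, collapse = "\n  "))
  merge_config(raw, default_config())
}

plog <- function(cfg, stage, msg) {
  if (identical(cfg$log, "quiet")) return(invisible())
  message(sprintf("[%s] %s", stage, msg))
}

stage_input <- function(path, stage, what) {
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("%s: missing input %s (%s)", stage, what, path))
  path
}

## deterministic sub-seeds derived from the global seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max %/% 2L, n)
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order — simulate (optional) ->
#' call-enhancers -> quantify -> diffactivity -> fragqc -> motifdev ->
#' aggregate — writing per-stage outputs and a provenance manifest
#' (parameters, seeds, output checksums) into `out_dir`. Reruns with an
#' identical configuration reproduce identical outputs.
#'
#' @param config Path to a YAML config or a config list (see
#'   [validate_config()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(cfg$seed, 16L)

  ## --- simulate / load inputs -------------------------------------------
  if (isTRUE(cfg$simulate$enabled)) {
    plog(cfg, "simulate", "generating synthetic locus set")
    sim <- cfg$simulate
    truth <- simulate_locus_set(seed = seeds[1], n_chroms = sim$n_chroms,
                                chrom_length = sim$chrom_length,
                                n_genes = sim$n_genes,
                                n_enhancers = sim$n_enhancers,
                                n_decoys = sim$n_decoys)
    paths <- write_locus_set(truth, file.path(out_dir, "simulate"))
    genes <- truth$genes
    peaks <- truth$peaks
    histone <- truth$histone_peaks
    blacklist <- truth$blacklist
    motif_sites <- truth$motif_sites
    chrom_lengths <- truth$chrom_lengths
    conds <- rep(truth$conditions, each = sim$n_replicates)
    sample_ids <- paste0(conds, "_r", rep(seq_len(sim$n_replicates),
                                          length(truth$conditions)))
    cov_seeds <- derive_seeds(seeds[2], length(conds))
    coverages <- lapply(seq_along(conds), function(i)
      simulate_nascent_coverage(truth, conds[i], depth = sim$depth,
                                seed = cov_seeds[i]))
    names(coverages) <- sample_ids
    fr <- simulate_fragments(truth, n_cells_per_cluster = sim$n_cells_per_cluster,
                             fragments_per_cell = sim$fragments_per_cell,
                             seed = seeds[3])
    fragments <- fr$fragments
    labels <- fr$labels
    write_fragments(fragments, file.path(out_dir, "simulate", "fragments.tsv"))
    write_cell_labels(labels, file.path(out_dir, "simulate", "labels.tsv"))
  } else {
    plog(cfg, "inputs", "loading external inputs")
    inp <- cfg$inputs
    peaks <- read_bed(stage_input(inp$peaks, "call-enhancers", "peaks"))
    genes <- read_gene_models(stage_input(inp$genes, "call-enhancers", "genes"),
                              if (nzchar(inp$exons)) inp$exons else NULL)
    histone <- if (nzchar(inp$histone)) read_bed(inp$histone) else NULL
    blacklist <- if (nzchar(inp$blacklist)) read_bed(inp$blacklist) else
      genomic_intervals(character(), integer(), integer())
    motif_sites <- read_bed(stage_input(inp$motif_sites, "motifdev",
                                        "motif_sites"))
    frag_path <- stage_input(inp$fragments, "fragqc", "fragments")
    fragments <- read_fragments(frag_path)
    labels <- read_cell_labels(stage_input(inp$labels, "fragqc", "labels"))
    chrom_lengths <- NULL  # inferred below
    cov <- read_stranded_coverage(
      stage_input(inp$plus_bedgraph, "call-enhancers", "plus_bedgraph"),
      stage_input(inp$minus_bedgraph, "call-enhancers", "minus_bedgraph"),
      infer_chrom_lengths(peaks, fragments))
    coverages <- list(sample1 = cov)
    chrom_lengths <- cov$chrom_lengths
    truth <- NULL
  }

  ## --- call-enhancers ----------------------------------------------------
  plog(cfg, "call-enhancers", "calling eRNA enhancers")
  pooled <- pool_coverage(coverages)
  ep <- cfg$enhancers
  cand <- call_enhancers(peaks, genes, pooled, histone_peaks = histone,
                         atac_peaks = peaks, flank = ep$flank,
                         max_ratio = ep$max_ratio, min_cpm = ep$min_cpm,
                         cluster_gap = ep$cluster_gap)
  utils::write.table(cand, file.path(out_dir, "enhancers.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  kept <- cand[cand$status == "kept", , drop = FALSE]
  write_bed(genomic_intervals(kept$chrom, kept$start, kept$end,
                              name = kept$id, score = kept$effective_count),
            file.path(out_dir, "enhancers_kept.bed"))

  ## --- quantify ----------------------------------------------------------
  plog(cfg, "quantify", sprintf("quantifying %d enhancers x %d samples",
                                nrow(kept), length(coverages)))
  enh_regions <- genomic_intervals(kept$chrom, kept$start, kept$end,
                                   name = kept$id)
  enh_counts <- vapply(coverages, function(cv)
    quantify_regions(cv, enh_regions, strand_mode = "effective"),
    numeric(nrow(enh_regions)))
  enh_counts <- round(matrix(enh_counts, nrow = nrow(enh_regions),
                             dimnames = list(kept$id, names(coverages))))
  write_count_matrix(enh_counts, file.path(out_dir, "enhancer_counts.tsv"))

  gene_counts <- vapply(coverages, function(cv)
    quantify_regions(cv, genes$body,
                     per_position_cap = cfg$quantify$per_position_cap,
                     exon_mask = genes$exons, strand_mode = "sense"),
    numeric(nrow(genes$body)))
  gene_counts <- round(matrix(gene_counts, nrow = nrow(genes$body),
                              dimnames = list(genes$body$name,
                                              names(coverages))))
  write_count_matrix(gene_counts, file.path(out_dir, "gene_counts.tsv"))

  ## --- diffactivity ------------------------------------------------------
  diff_res <- NULL
  lrt_res <- NULL
  if (length(coverages) >= 4) {
    plog(cfg, "diffactivity", "NB QL F-test on enhancer counts")
    dm <- filter_low_expression(enh_counts, cpm_cutoff = cfg$diff$count_cutoff,
                                min_samples = cfg$diff$min_samples,
                                unit = "raw")
    grp <- sub("_r[0-9]+$", "", colnames(dm))
    diff_res <- nbql_test(dm, grp)
    utils::write.table(diff_res, file.path(out_dir, "diff_enhancers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gm <- filter_low_expression(gene_counts, cpm_cutoff = 0.5,
                                min_samples = cfg$diff$min_samples,
                                unit = "cpm")
    lrt_res <- lrt_any_change(gm, grp)
    sig <- lrt_res$feature_id[lrt_res$q_value < cfg$diff$lrt_fdr]
    if (length(sig) >= cfg$diff$kmeans_k) {
      z <- t(scale(t(log1p(cpm_matrix(gm[sig, , drop = FALSE])))))
      z[!is.finite(z)] <- 0
      lrt_res$cluster <- NA_integer_
      lrt_res$cluster[match(sig, lrt_res$feature_id)] <-
        kmeans_profiles(z, k = cfg$diff$kmeans_k, seed = seeds[4])
    }
    utils::write.table(lrt_res, file.path(out_dir, "diff_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## --- fragqc ------------------------------------------------------------
  plog(cfg, "fragqc", "per-cell fragment QC")
  metrics <- per_cell_metrics(fragments, peaks, blacklist, genes,
                              flank = cfg$fragqc$tss_flank)
  utils::write.table(metrics, file.path(out_dir, "cell_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  kept_bc <- qc_filter(metrics)
  writeLines(kept_bc, file.path(out_dir, "cells_kept.txt"))

  ## --- motifdev ----------------------------------------------------------
  plog(cfg, "motifdev", sprintf("motif deviations over %d cells",
                                length(kept_bc)))
  pcm <- build_peak_matrix(fragments, peaks, kept_bc)
  msets <- motif_sets_from_sites(pcm, motif_sites)
  dev <- motif_deviation_scores(pcm, msets, B = cfg$motifs$B,
                                seed = seeds[5])
  write_count_matrix(round(dev$z, 4), file.path(out_dir, "motif_z.tsv"),
                     id_col = "motif")
  cmot <- cluster_specific_motifs(dev, labels,
                                  lfc_threshold = cfg$motifs$lfc_threshold,
                                  fdr = cfg$motifs$fdr)
  utils::write.table(cmot, file.path(out_dir, "cluster_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## --- aggregate ---------------------------------------------------------
  plog(cfg, "aggregate", "state-specific regions and signal matrices")
  ag <- cfg$aggregate
  ssr <- state_specific_regions(pcm, labels, min_fc = ag$min_fc,
                                fdr = ag$fdr, top_n = ag$top_n)
  utils::write.table(ssr$table, file.path(out_dir, "state_regions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pb <- pseudobulk_coverage(fragments, labels, chrom_lengths)
  st1 <- names(ssr$top)[1]
  sel <- unique(c(ssr$top[[st1]]$up, ssr$top[[st1]]$down))
  profiles <- NULL
  if (length(sel)) {
    ctr <- pcm$peaks[match(sel, pcm$peaks$name), , drop = FALSE]
    sm <- signal_matrix(pb[[st1]], ctr, flank = ag$flank,
                        bin_size = ag$bin_size)
    utils::write.table(round(sm$values, 5),
                       file.path(out_dir, "signal_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    dir_of <- ifelse(sm$region_ids %in% ssr$top[[st1]]$up, "up", "down")
    profiles <- average_profile(sm, dir_of)
    utils::write.table(round(profiles, 5),
                       file.path(out_dir, "average_profiles.tsv"),
                       sep = "\t", quote = FALSE)
  }

  ## --- manifest ----------------------------------------------------------
  outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outs <- setdiff(outs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package = "groatac",
    version = as.character(utils::packageVersion("groatac")),
    config = cfg,
    seeds = seeds,
    outputs = lapply(stats::setNames(outs, sub(paste0("^", out_dir, "/?"), "",
                                               outs)),
                     function(f) unname(tools::md5sum(f)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(candidates = cand, enhancer_counts = enh_counts,
                 diff = diff_res, lrt = lrt_res, metrics = metrics,
                 kept_barcodes = kept_bc, deviations = dev,
                 cluster_motifs = cmot, state_regions = ssr,
                 profiles = profiles, manifest = manifest,
                 truth = if (exists("truth")) truth else NULL))
}

pool_coverage <- function(coverages) {
  base <- coverages[[1]]
  if (length(coverages) == 1) return(base)
  for (cv in coverages[-1]) {
    for (ch in names(base$chrom_lengths)) {
      base$plus[[ch]] <- base$plus[[ch]] + cv$plus[[ch]]
      base$minus[[ch]] <- base$minus[[ch]] + cv$minus[[ch]]
    }
  }
  base
}

infer_chrom_lengths <- function(peaks, fragments) {
  chroms <- union(unique(peaks$chrom), unique(fragments$chrom))
  out <- lapply(chroms, function(ch)
    max(peaks$end[peaks$chrom == ch], fragments$end[fragments$chrom == ch],
        0L) + 10000L)
  stats::setNames(out, chroms)
}
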
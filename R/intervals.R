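#' Construct a table of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Strand is one of `"+"`, `"-"` or `"*"`
#' (unstranded).
#'
#' @param chrom Character vector of chromosome names.
#' @param start Integer vector, 0-based inclusive start.
#' @param end Integer vector, exclusive end (`end > start`).
#' @param strand Strand per interval; recycled. Default unstranded.
#' @param name Optional labels; recycled.
#' @param score Optional numeric scores; recycled.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, `score`, one row per interval.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*",
                              name = NA_character_, score = NA_real_) {
  n <- max(length(chrom), length(start), length(end))
  x <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    name = rep_len(as.character(name), n),
    score = rep_len(as.numeric(score), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(x)
  x
}

validate_intervals <- function(x) {
  stopifnot(is.data.frame(x))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(x)))
    stop("interval table must have columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end))
    stop("non-integer interval coordinates")
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad))
    stop(sprintf("invalid interval at row %d: start=%s end=%s",
                 bad[1], x$start[bad[1]], x$end[bad[1]]))
  if (any(!nzchar(x$chrom))) stop("empty chromosome name")
  if ("strand" %in% names(x) && !all(x$strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*'")
  invisible(x)
}

#' @return Integer widths (`end - start`).
#' @rdname genomic_intervals
#' @param x An interval table.
#' @export
interval_width <- function(x) x$end - x$start

## Convert a 0-based half-open interval table to a GRanges (1-based closed)
## for overlap arithmetic via IRanges machinery.
as_granges <- function(x) {
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

## Hits between two 0-based interval tables; returns the findOverlaps Hits
## object (queryHits/subjectHits index rows of a and b).
interval_overlaps <- function(a, b, ignore_strand = TRUE) {
  ## disjoint chromosome sets are legitimate (e.g. sites on other chroms);
  ## silence the seqlevel-merge notice
  suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(a), as_granges(b),
                                ignore.strand = ignore_strand))
}

## Per-row largest base-pair overlap of `a` with any interval in `b`.
max_overlap_bp <- function(a, b) {
  out <- numeric(nrow(a))
  if (nrow(a) == 0 || nrow(b) == 0) return(out)
  h <- interval_overlaps(a, b)
  if (length(h) == 0) return(out)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  agg <- tapply(ov, qi, max)
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Construct gene models
#'
#' A gene model is a stranded gene-body interval plus its TSS (the
#' strand-aware 5' end), exon sub-intervals and a promoter window derived
#' from the TSS (upstream 1000 bp, downstream 500 bp in the transcribed
#' orientation).
#'
#' @param body Interval table with mandatory `+`/`-` strand, one row per gene,
#'   with non-empty `name`.
#' @param exons Optional interval table with a `name` column matching gene
#'   names; exons must lie within the gene body.
#' @param promoter_up,promoter_down Promoter extent up/downstream of the TSS
#'   in bp.
#' @return A list with elements `body` (with added `tss` column), `exons`,
#'   and `promoters` (interval table, one row per gene).
#' @export
gene_models <- function(body, exons = NULL, promoter_up = 1000L,
                        promoter_down = 500L) {
  validate_intervals(body)
  if (nrow(body) > 0 && !all(body$strand %in% c("+", "-")))
    stop("gene bodies must be stranded")
  if (anyDuplicated(body$name)) stop("duplicate gene names")
  tss <- ifelse(body$strand == "+", body$start, body$end - 1L)
  body$tss <- as.integer(tss)
  prom_start <- ifelse(body$strand == "+", tss - promoter_up,
                       tss - promoter_down + 1L)
  prom_end <- ifelse(body$strand == "+", tss + promoter_down,
                     tss + promoter_up + 1L)
  promoters <- data.frame(
    chrom = body$chrom,
    start = as.integer(pmax(0L, prom_start)),
    end = as.integer(prom_end),
    strand = body$strand,
    name = body$name,
    score = NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(exons) && nrow(exons) > 0) {
    validate_intervals(exons)
    m <- match(exons$name, body$name)
    if (anyNA(m)) stop("exon with unknown gene name")
    inside <- exons$start >= body$start[m] & exons$end <= body$end[m]
    if (!all(inside)) stop("exon outside its gene body")
    o <- order(exons$name, exons$start)
    exons <- exons[o, , drop = FALSE]
    rownames(exons) <- NULL
  } else {
    exons <- genomic_intervals(character(), integer(), integer())
  }
  structure(list(body = body, exons = exons, promoters = promoters),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("<gene_models> %d genes, %d exon records\n",
              nrow(x$body), nrow(x$exons)))
  invisible(x)
}
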
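#' Read genomic intervals from a BED file
#'
#' BED coordinates (0-based, half-open) are preserved verbatim. Strand is
#' taken from column 6 when present, otherwise unstranded. Lines starting
#' with `#`, `track` or `browser` are skipped.
#'
#' @param path Path to a BED3+ file (plain text).
#' @param expected_columns Optional minimum column count to enforce.
#' @return Interval table as from [genomic_intervals()], in file order.
#' @export
read_bed <- function(path, expected_columns = 3L) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(genomic_intervals(character(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < max(3L, expected_columns)))
    stop(sprintf("BED parse error at line %d: expected >= %d columns",
                 lineno[which(ncol < max(3L, expected_columns))[1]],
                 max(3L, expected_columns)))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: invalid coordinates", lineno[bad[1]]))
  strand <- if (max(ncol) >= 6) get(6) else rep(NA_character_, length(lines))
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  score <- if (max(ncol) >= 5) suppressWarnings(as.numeric(get(5))) else NA_real_
  name <- if (max(ncol) >= 4) get(4) else NA_character_
  genomic_intervals(get(1), start, end, strand = strand,
                    name = name, score = score)
}

#' Write intervals as BED
#'
#' @param x Interval table.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  name <- if ("name" %in% names(x)) x$name else NA
  score <- if ("score" %in% names(x)) x$score else NA
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  out <- data.frame(x$chrom, x$start, x$end,
                    ifelse(is.na(name), ".", name),
                    ifelse(is.na(score), 0, score),
                    ifelse(strand == "*", ".", strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

new_stranded_coverage <- function(plus, minus, chrom_lengths) {
  stopifnot(identical(names(plus), names(chrom_lengths)),
            identical(names(minus), names(chrom_lengths)))
  for (ch in names(chrom_lengths)) {
    stopifnot(length(plus[[ch]]) == chrom_lengths[[ch]],
              length(minus[[ch]]) == chrom_lengths[[ch]])
    if (any(plus[[ch]] < 0) || any(minus[[ch]] < 0))
      stop("coverage values must be non-negative")
  }
  structure(list(plus = plus, minus = minus,
                 chrom_lengths = chrom_lengths),
            class = "stranded_coverage")
}

#' @export
print.stranded_coverage <- function(x, ...) {
  tot_p <- sum(vapply(x$plus, sum, 0))
  tot_m <- sum(vapply(x$minus, sum, 0))
  cat(sprintf("<stranded_coverage> %d chroms (%.0f bp), plus %.1f / minus %.1f total signal\n",
              length(x$chrom_lengths), sum(unlist(x$chrom_lengths)), tot_p, tot_m))
  invisible(x)
}

parse_bedgraph_dense <- function(path, chrom_lengths, label) {
  vecs <- lapply(chrom_lengths, function(L) numeric(L))
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                      colClasses = c("character", "integer", "integer", "numeric")),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e))) NULL else stop(e)
    })
  if (is.null(df) || nrow(df) == 0) return(vecs)
  names(df) <- c("chrom", "start", "end", "value")
  if (any(!df$chrom %in% names(chrom_lengths)))
    stop(label, " bedGraph: unknown chromosome ",
         df$chrom[!df$chrom %in% names(chrom_lengths)][1])
  if (any(df$start < 0 | df$start >= df$end))
    stop(label, " bedGraph: invalid interval")
  if (any(df$end > unlist(chrom_lengths)[df$chrom]))
    stop(label, " bedGraph: record beyond chromosome length")
  for (ch in unique(df$chrom)) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1 && any(d$start[-1] < d$end[-nrow(d)]))
      stop(label, " bedGraph: overlapping records on ", ch)
    v <- vecs[[ch]]
    for (i in seq_len(nrow(d)))
      v[(d$start[i] + 1L):d$end[i]] <- abs(d$value[i])
    vecs[[ch]] <- v
  }
  vecs
}

#' Read strand-specific base-level coverage from two bedGraph files
#'
#' Produces dense per-base signal vectors per chromosome. Uncovered bases are
#' zero. Minus-strand values are stored as non-negative magnitudes (the sign
#' convention of browser tracks is stripped).
#'
#' @param plus_path,minus_path bedGraph files (0-based half-open,
#'   non-overlapping records within each file).
#' @param chrom_lengths Named integer vector/list, chromosome lengths in bp.
#' @return A `stranded_coverage` object: lists `plus` and `minus` of per-base
#'   numeric vectors plus `chrom_lengths`.
#' @export
read_stranded_coverage <- function(plus_path, minus_path, chrom_lengths) {
  chrom_lengths <- as.list(chrom_lengths)
  plus <- parse_bedgraph_dense(plus_path, chrom_lengths, "plus")
  minus <- parse_bedgraph_dense(minus_path, chrom_lengths, "minus")
  new_stranded_coverage(plus, minus, chrom_lengths)
}

#' Write one strand of a coverage object as bedGraph
#'
#' Runs of equal nonzero value are collapsed to single records.
#'
#' @param cov A `stranded_coverage` object.
#' @param strand `"plus"` or `"minus"`.
#' @param path Output path.
#' @export
write_bedgraph <- function(cov, strand = c("plus", "minus"), path) {
  strand <- match.arg(strand)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(cov$chrom_lengths)) {
    v <- cov[[strand]][[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      df <- data.frame(ch, starts[keep], ends[keep],
                       format(r$values[keep], trim = TRUE, scientific = FALSE))
      utils::write.table(df, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a 10x-convention fragments file
#'
#' Five tab-separated columns: chrom, start, end, barcode, count. Lines
#' beginning `#` are skipped; a missing fifth column defaults to count 1.
#' Plain or gzip-compressed input is accepted.
#'
#' @param path Path to the fragments TSV.
#' @return `data.frame` with columns `chrom`, `start`, `end`, `barcode`,
#'   `count`, in file order.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      barcode = character(), count = integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4))
    stop(sprintf("fragments parse error at line %d: expected >= 4 columns",
                 lineno[which(nf < 4)[1]]))
  get <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(get(2)))
  end <- suppressWarnings(as.integer(get(3)))
  count <- suppressWarnings(as.integer(get(5)))
  count[is.na(count)] <- 1L
  bad <- which(is.na(start) | is.na(end) | start < 0 | end <= start)
  if (length(bad))
    stop(sprintf("fragments parse error at line %d: non-positive length",
                 lineno[bad[1]]))
  if (any(count < 1))
    stop(sprintf("fragments parse error at line %d: count < 1",
                 lineno[which(count < 1)[1]]))
  data.frame(chrom = get(1), start = start, end = end,
             barcode = get(4), count = count, stringsAsFactors = FALSE)
}

#' Write fragments as a 5-column TSV
#' @param frags Fragment table (`chrom`, `start`, `end`, `barcode`, `count`).
#' @param path Output path; `.gz` suffix writes gzip-compressed.
#' @export
write_fragments <- function(frags, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(frags[, c("chrom", "start", "end", "barcode", "count")],
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' First column = feature ids, header row = sample ids.
#'
#' @param path TSV path.
#' @return Integer-like matrix, features x samples.
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          row.names = 1)
  m <- as.matrix(df)
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids")
  if (any(m < 0)) stop("negative counts")
  m
}

#' Write a count matrix as TSV
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the feature-id column.
#' @export
write_count_matrix <- function(m, path, id_col = "feature") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a barcode-to-label table
#'
#' Two or three tab-separated columns with header: `barcode`, `label`, and
#' optionally `condition`.
#'
#' @param path TSV path.
#' @return `data.frame` with unique barcodes and non-empty labels.
#' @export
read_cell_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  if (!all(c("barcode", "label") %in% names(df)))
    stop("label table needs columns 'barcode' and 'label'")
  if (anyDuplicated(df$barcode)) stop("duplicate barcodes in label table")
  if (any(!nzchar(df$label))) stop("empty label")
  df
}

#' @rdname read_cell_labels
#' @param labels Label table.
#' @export
write_cell_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
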
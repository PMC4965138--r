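#' Read a FASTQ file into a bs_reads table
#'
#' @param path FASTQ path (phred+33 qualities).
#' @return a `bs_reads` data.frame with columns `id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    am_stop("ampliMeth_missing_file", "FASTQ not found: %s", path)
  }
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  out <- data.frame(id = sub("\\s.*$", "", names(x)),
                    sequence = as.character(x),
                    quality = as.character(S4Vectors::mcols(x)$qualities),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("bs_reads", "data.frame")
  out
}

#' Write a bs_reads table as FASTQ
#'
#' @param reads a `bs_reads` data.frame.
#' @param path output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Clip low-quality 3' tails
#'
#' Removes the contiguous run of trailing bases whose phred quality falls
#' below `q_min`; trimming stops at the rightmost base with quality
#' `>= q_min`, so internal low-quality bases are retained. The trimmed read
#' is always a prefix of the input.
#'
#' @param reads a `bs_reads` data.frame.
#' @param q_min phred threshold; bases strictly below it are clipped.
#' @return the trimmed `bs_reads` (reads may become empty; see
#'   [filter_min_length()] / [drop_empty_reads()]).
#' @export
#' @examples
#' r <- data.frame(id = "r1", sequence = "ACGT",
#'                 quality = ampliMeth:::int_to_phred(c(30, 30, 15, 12)))
#' trim_3prime(r)$sequence  # "AC"
trim_3prime <- function(reads, q_min = 20L) {
  keep_len <- vapply(reads$quality, function(q) {
    v <- phred_to_int(q)
    k <- length(v)
    while (k >= 1L && v[k] < q_min) k <- k - 1L
    k
  }, 0L, USE.NAMES = FALSE)
  reads$sequence <- substr(reads$sequence, 1L, keep_len)
  reads$quality <- substr(reads$quality, 1L, keep_len)
  reads
}

#' Filter reads by minimum length
#'
#' @param reads a `bs_reads` data.frame.
#' @param m minimum length in bp; reads shorter than `m` are dropped,
#'   relative order is preserved. `m = 0` retains everything.
#' @return the filtered `bs_reads`.
#' @export
filter_min_length <- function(reads, m = 0L) {
  if (m < 0L) am_stop("ampliMeth_bad_config", "minimum length must be >= 0")
  out <- reads[nchar(reads$sequence) >= m, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop reads trimmed to length zero
#'
#' @param reads a `bs_reads` data.frame.
#' @return reads with at least one base.
#' @export
drop_empty_reads <- function(reads) filter_min_length(reads, 1L)

#' Summarize a read set
#'
#' Computes the per-file summary statistics reported before and after
#' quality control: read count, length distribution, GC fraction (N counts
#' as non-GC), per-position mean quality and the number of exact-sequence
#' duplicate reads (occurrences beyond the first).
#'
#' @param reads a `bs_reads` data.frame.
#' @return an object of class `qc_summary`.
#' @export
qc_summary <- function(reads) {
  n <- nrow(reads)
  lens <- nchar(reads$sequence)
  total_bases <- sum(lens)
  gc <- if (total_bases == 0L) NA_real_ else {
    counts <- colSums(Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(reads$sequence)))
    unname((counts[["G"]] + counts[["C"]]) / total_bases)
  }
  maxlen <- if (n == 0L) 0L else max(lens)
  pos_qual <- if (maxlen == 0L) numeric(0) else {
    sums <- numeric(maxlen); cnts <- integer(maxlen)
    for (q in reads$quality) {
      v <- phred_to_int(q)
      if (length(v) > 0L) {
        idx <- seq_along(v)
        sums[idx] <- sums[idx] + v
        cnts[idx] <- cnts[idx] + 1L
      }
    }
    ifelse(cnts > 0L, sums / cnts, NA_real_)
  }
  structure(list(
    read_count = n,
    length_min = if (n == 0L) NA_integer_ else min(lens),
    length_mean = if (n == 0L) NA_real_ else mean(lens),
    length_max = if (n == 0L) NA_integer_ else max(lens),
    length_histogram = table(lens),
    gc_fraction = gc,
    per_position_mean_quality = pos_qual,
    duplicate_count = sum(duplicated(reads$sequence))
  ), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("qc_summary: %d reads, length %s-%s (mean %.1f), GC %.3f, %d duplicates\n",
              x$read_count,
              ifelse(is.na(x$length_min), "-", x$length_min),
              ifelse(is.na(x$length_max), "-", x$length_max),
              ifelse(is.na(x$length_mean), NA, x$length_mean),
              ifelse(is.na(x$gc_fraction), NA, x$gc_fraction),
              x$duplicate_count))
  invisible(x)
}

#' Write a before/after QC comparison report
#'
#' Renders the two summaries side by side as a TSV so the effect of 3'
#' clipping and length filtering can be inspected.
#'
#' @param before,after `qc_summary` objects.
#' @param path output TSV path.
#' @return invisibly, the report data.frame.
#' @export
qc_report <- function(before, after, path) {
  metric <- c("read_count", "length_min", "length_mean", "length_max",
              "gc_fraction", "duplicate_count", "mean_quality")
  pull <- function(s) c(s$read_count, s$length_min, s$length_mean, s$length_max,
                        s$gc_fraction, s$duplicate_count,
                        if (length(s$per_position_mean_quality) == 0L) NA_real_
                        else mean(s$per_position_mean_quality, na.rm = TRUE))
  b <- pull(before); a <- pull(after)
  df <- data.frame(metric = metric, before = b, after = a, delta = a - b,
                   stringsAsFactors = FALSE)
  tryCatch(write_tsv(df, path),
           error = function(e) am_stop("ampliMeth_unwritable",
                                       "cannot write QC report: %s", path))
  invisible(df)
}
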
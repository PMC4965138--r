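#' Call per-CpG methylation states from one alignment
#'
#' Reads originating from the original top strand (`OT`/`CTOT`) report
#' methylation at the C of each CpG: an unconverted `C` means methylated, a
#' `T` means the cytosine was converted, i.e. unmethylated. Bottom-strand
#' reads (`OB`/`CTOB`) report the symmetric cytosine through the forward
#' `G` of the CpG: `G` methylated, `A` unmethylated. Any other base, an `N`
#' or a gap at the informative position yields `nocall`. Only CpG sites
#' whose informative base lies inside the aligned span are reported.
#'
#' @param alignment an `amplicon_alignment` record (see [align_reads()]).
#' @param entry the matching `converted_index` entry (carries the CpG
#'   offsets of the target).
#' @return data.frame with columns `read_id`, `target_name`, `offset`,
#'   `genome_pos`, `state` (`methylated`/`unmethylated`/`nocall`),
#'   `strand_of_call` (`+` for OT/CTOT, `-` for OB/CTOB).
#' @export
call_read <- function(alignment, entry) {
  plus <- alignment$strand_label %in% c("OT", "CTOT")
  sites <- entry$cpg
  # informative base: the C (offset) on '+', the G (offset+1) on '-'
  info_off <- sites$offset + if (plus) 0L else 1L
  covered <- info_off >= alignment$target_start & info_off < alignment$target_end
  sites <- sites[covered, , drop = FALSE]
  info_off <- info_off[covered]
  if (nrow(sites) == 0L) return(empty_observations())
  base <- alignment$base_at[info_off - alignment$target_start + 1L]
  state <- if (plus) {
    ifelse(is.na(base), "nocall",
           ifelse(base == "C", "methylated",
                  ifelse(base == "T", "unmethylated", "nocall")))
  } else {
    ifelse(is.na(base), "nocall",
           ifelse(base == "G", "methylated",
                  ifelse(base == "A", "unmethylated", "nocall")))
  }
  data.frame(read_id = alignment$read_id, target_name = alignment$target_name,
             offset = sites$offset, genome_pos = sites$genome_pos,
             state = state, strand_of_call = if (plus) "+" else "-",
             stringsAsFactors = FALSE)
}

empty_observations <- function() {
  data.frame(read_id = character(), target_name = character(),
             offset = integer(), genome_pos = integer(),
             state = character(), strand_of_call = character(),
             stringsAsFactors = FALSE)
}

#' CpH side-channel calls from one alignment
#'
#' Applies the same base-calling rule at cytosine positions outside CpG
#' context: forward-strand `C` not followed by `G` for top-strand reads,
#' forward `G` not preceded by `C` (a bottom-strand CpH cytosine) for
#' bottom-strand reads. Since CpH methylation is rare in mammals, the
#' methylated fraction of this channel estimates bisulfite conversion
#' failure. Reported separately; never mixed into the CpG table.
#'
#' @inheritParams call_read
#' @return data.frame in the [call_read()] layout (offset is the position
#'   of the informative base itself).
#' @export
cph_calls <- function(alignment, entry) {
  plus <- alignment$strand_label %in% c("OT", "CTOT")
  ch <- strsplit(entry$seq, "")[[1L]]
  n <- length(ch)
  if (plus) {
    off <- which(ch == "C" & c(ch[-1L], "") != "G") - 1L
  } else {
    off <- which(ch == "G" & c("", ch[-n]) != "C") - 1L
  }
  covered <- off >= alignment$target_start & off < alignment$target_end
  off <- off[covered]
  if (length(off) == 0L) return(empty_observations())
  base <- alignment$base_at[off - alignment$target_start + 1L]
  state <- if (plus) {
    ifelse(is.na(base), "nocall",
           ifelse(base == "C", "methylated",
                  ifelse(base == "T", "unmethylated", "nocall")))
  } else {
    ifelse(is.na(base), "nocall",
           ifelse(base == "G", "methylated",
                  ifelse(base == "A", "unmethylated", "nocall")))
  }
  data.frame(read_id = alignment$read_id, target_name = alignment$target_name,
             offset = off, genome_pos = entry$start + off,
             state = state, strand_of_call = if (plus) "+" else "-",
             stringsAsFactors = FALSE)
}

#' Collect observations from all accepted alignments
#'
#' @param aln an `amplicon_alignments` object.
#' @param index the `converted_index` used for alignment.
#' @param channel `"cpg"` for [call_read()] observations, `"cph"` for the
#'   [cph_calls()] side channel.
#' @return one data.frame of observations across all reads.
#' @export
call_alignments <- function(aln, index, channel = c("cpg", "cph")) {
  channel <- match.arg(channel)
  fun <- if (channel == "cpg") call_read else cph_calls
  obs <- lapply(aln$alignments, function(a) fun(a, index[[a$target_name]]))
  if (length(obs) == 0L) return(empty_observations())
  out <- do.call(rbind, obs)
  rownames(out) <- NULL
  out
}

#' Accumulate observations into a per-CpG call matrix
#'
#' Counts methylated and unmethylated observations per (sample, target,
#' CpG, call strand). `nocall` observations are tallied separately and
#' excluded from counts and percentages. Every CpG site of every target is
#' present on both call strands even with zero observations (percent is
#' then `NA`), so downstream filters and tables see the complete grid.
#'
#' @param observations a [call_read()]-layout data.frame; may carry a
#'   `sample` column (defaults to `"sample1"`).
#' @param targets the `target_set` (defines the full site grid).
#' @param samples optional character vector fixing the sample universe and
#'   order (useful when some samples produced no observations).
#' @return a `cpg_call_matrix` data.frame: `sample`, `target_name`,
#'   `offset`, `genome_pos`, `strand_of_call`, `n_meth`, `n_unmeth`,
#'   `n_nocall`, `coverage`, `percent`, `filtered`, `filter_reason`.
#' @export
accumulate <- function(observations, targets, samples = NULL) {
  if (is.null(observations$sample)) {
    observations$sample <- rep("sample1", nrow(observations))
  }
  if (is.null(samples)) {
    samples <- unique(observations$sample)
    if (length(samples) == 0L) samples <- "sample1"
  }
  grid <- do.call(rbind, lapply(seq_len(nrow(targets)), function(i) {
    enumerate_cpg_sites(targets[i, , drop = FALSE])
  }))
  if (is.null(grid) || nrow(grid) == 0L) {
    out <- data.frame(sample = character(), target_name = character(),
                      offset = integer(), genome_pos = integer(),
                      strand_of_call = character(), n_meth = integer(),
                      n_unmeth = integer(), n_nocall = integer(),
                      coverage = integer(), percent = numeric(),
                      filtered = logical(), filter_reason = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("cpg_call_matrix", "data.frame")
    return(out)
  }
  grid <- merge(expand.grid(sample = samples, strand_of_call = c("+", "-"),
                            stringsAsFactors = FALSE),
                grid, by = NULL)
  key <- function(d) paste(d$sample, d$target_name, d$offset, d$strand_of_call,
                           sep = "\r")
  gk <- key(grid)
  tab <- function(st) {
    o <- observations[observations$state == st, , drop = FALSE]
    cnt <- table(factor(key(o), levels = gk))
    as.integer(cnt)
  }
  out <- data.frame(sample = grid$sample, target_name = grid$target_name,
                    offset = grid$offset, genome_pos = grid$genome_pos,
                    strand_of_call = grid$strand_of_call,
                    n_meth = tab("methylated"), n_unmeth = tab("unmethylated"),
                    n_nocall = tab("nocall"), stringsAsFactors = FALSE)
  out$coverage <- out$n_meth + out$n_unmeth
  out$percent <- ifelse(out$coverage > 0, 100 * out$n_meth / out$coverage, NA_real_)
  out$filtered <- FALSE
  out$filter_reason <- ""
  o <- order(match(out$sample, samples), match(out$target_name, targets$name),
             out$offset, out$strand_of_call)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cpg_call_matrix", "data.frame")
  out
}

#' Write a bedGraph-style per-site file
#'
#' Emits the per-CpG intermediate in BED-family coordinates (0-based,
#' half-open) with methylation percent and raw counts, one file per sample.
#'
#' @param mat a `cpg_call_matrix` (typically one sample's rows).
#' @param targets the `target_set` (for chromosome labels).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(mat, targets, path) {
  chrom <- targets$chrom[match(mat$target_name, targets$name)]
  df <- data.frame(chrom = chrom, start = mat$genome_pos - 1L,
                   end = mat$genome_pos,
                   percent = round(ifelse(is.na(mat$percent), -1, mat$percent), 3),
                   n_meth = mat$n_meth, n_unmeth = mat$n_unmeth,
                   strand = mat$strand_of_call, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
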
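# Shared fixture builders for the test suite. Everything is generated in
# code; no binary fixtures.

phred <- function(v) ampliMeth:::int_to_phred(v)

mk_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n) phred(rep(35L, n)), "")
  }
  out <- data.frame(id = ids, sequence = seqs, quality = quals,
                    stringsAsFactors = FALSE)
  class(out) <- c("bs_reads", "data.frame")
  out
}

mk_target <- function(sequence, name = "amp1", chrom = "chrT", start = 101L,
                      strand = "+") {
  out <- data.frame(name = name, chrom = chrom, start = as.integer(start),
                    end = as.integer(start + nchar(sequence) - 1L),
                    strand = strand, annotation = NA_character_,
                    sequence = sequence, stringsAsFactors = FALSE)
  class(out) <- c("target_set", "data.frame")
  out
}

bind_targets <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("target_set", "data.frame")
  out
}

bind_targets2 <- function(lst) do.call(bind_targets, lst)

# run expr under a fixed seed, restoring the session RNG afterwards
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Hand-built call-matrix rows for the filter tests.
mk_call_matrix <- function(coverage, sample = "s1", target = "amp1",
                           strand = "+", percent_meth = 0.5) {
  n <- length(coverage)
  n_meth <- as.integer(round(coverage * percent_meth))
  out <- data.frame(sample = sample, target_name = target,
                    offset = seq_len(n) * 10L,
                    genome_pos = 100L + seq_len(n) * 10L,
                    strand_of_call = strand,
                    n_meth = n_meth, n_unmeth = as.integer(coverage) - n_meth,
                    n_nocall = 0L, coverage = as.integer(coverage),
                    percent = ifelse(coverage > 0, 100 * n_meth / coverage, NA),
                    filtered = FALSE, filter_reason = "",
                    stringsAsFactors = FALSE)
  class(out) <- c("cpg_call_matrix", "data.frame")
  out
}

# A hand-built alignment record (perfect, gap-free placement).
mk_alignment <- function(read, target_seq, strand_label = "OT",
                         target_start = 0L, read_id = "r1",
                         target_name = "amp1") {
  structure(list(read_id = read_id, target_name = target_name,
                 strand_label = strand_label, score = nchar(read),
                 identity = 1,
                 target_start = as.integer(target_start),
                 target_end = as.integer(target_start + nchar(read)),
                 oriented_read = read,
                 base_at = strsplit(read, "")[[1]],
                 cigar = paste0(nchar(read), "M")),
            class = "amplicon_alignment")
}
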
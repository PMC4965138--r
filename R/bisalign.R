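#' Build the converted-space index of a target set
#'
#' Bisulfite alignment works in three-letter space: every target's forward
#' sequence is stored alongside its full C-to-T conversion (the space in
#' which original-top-strand reads align) and its full G-to-A conversion
#' (original-bottom space). CpG site offsets are precomputed per target.
#'
#' @param targets a `target_set` with sequences attached.
#' @return an object of class `converted_index`: a named list with one entry
#'   per target holding `name`, `strand`, `start`, `chrom`, `seq`, `ct`,
#'   `ga`, `length` and `cpg` (the [enumerate_cpg_sites()] table).
#' @export
#' @examples
#' t <- random_target(length_bp = 60, n_cpg = 2)
#' idx <- build_converted_index(t)
#' idx[[1]]$ct  # all C replaced by T
build_converted_index <- function(targets) {
  if (anyNA(targets$sequence)) {
    am_stop("ampliMeth_no_sequence", "all targets need attached sequences")
  }
  entries <- lapply(seq_len(nrow(targets)), function(i) {
    t <- targets[i, , drop = FALSE]
    list(name = t$name, chrom = t$chrom, start = t$start, strand = t$strand,
         seq = t$sequence, ct = ct_convert(t$sequence),
         ga = ga_convert(t$sequence), length = nchar(t$sequence),
         cpg = enumerate_cpg_sites(t))
  })
  names(entries) <- targets$name
  structure(entries, class = "converted_index")
}

# Substitution matrix over the observed alphabet: N is always a mismatch.
align_submat <- function(match = 1, mismatch = -3) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5L, 5L, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", ] <- mismatch; m[, "N"] <- mismatch
  m
}

#' Default alignment scoring
#'
#' Match +1, mismatch -3, gap opening -5, gap extension -1. The low
#' extension cost deliberately tolerates the one-base homopolymer length
#' errors characteristic of semiconductor sequencing.
#'
#' @param match,mismatch,gap_opening,gap_extension scoring parameters;
#'   gap penalties are given as positive costs.
#' @return a named list consumed by [align_reads()].
#' @export
align_scoring <- function(match = 1, mismatch = -3,
                          gap_opening = 5, gap_extension = 1) {
  list(match = match, mismatch = mismatch,
       gap_opening = gap_opening, gap_extension = gap_extension)
}

# The candidate strand states tried per library. `rc` marks states whose
# read must be reverse-complemented into forward target orientation;
# `space` names the converted space of both read and target.
strand_states <- function(library) {
  st <- data.frame(
    label = c("OT", "CTOT", "CTOB", "OB"),
    rc    = c(FALSE, TRUE, FALSE, TRUE),
    space = c("ct", "ct", "ga", "ga"),
    stringsAsFactors = FALSE)
  if (library == "DIR") st[st$label %in% c("OT", "OB"), ] else st
}

#' Align reads to amplicon targets in converted space
#'
#' For every read, candidate semi-global alignments (read global, target
#' ends free, affine gaps) are computed for each target and strand state:
#' `OT` aligns the C-to-T-converted read against the C-to-T target, `CTOT`
#' the converted reverse complement against the same space, and `CTOB`/`OB`
#' the G-to-A-converted read / reverse complement against the G-to-A
#' target. Directional libraries try only `OT` and `OB`. The single
#' best-scoring candidate is accepted if it reaches `min_identity`
#' (fraction of identical alignment columns in converted space) and spans
#' at least `min_aligned_length` target bases; an exact score tie between
#' the top two candidates is reported as `ambiguous`, anything below
#' threshold as `unmapped`. Ties are only declared between candidates that
#' would themselves be accepted; tied below-threshold candidates are
#' `unmapped`.
#'
#' @param reads a `bs_reads` data.frame (empty reads must be dropped first).
#' @param index a [build_converted_index()] result.
#' @param library `"NONDIR"` (four strand states) or `"DIR"` (two).
#' @param min_identity minimum converted-space identity of an accepted
#'   alignment.
#' @param min_aligned_length minimum aligned target span in bp.
#' @param scoring an [align_scoring()] list.
#' @return an object of class `amplicon_alignments`: list with `summary`
#'   (data.frame: `read_id`, `status` in mapped/ambiguous/unmapped,
#'   `target_name`, `strand_label`, `score`, `identity`, `target_start`,
#'   `target_end` as 0-based half-open offsets) and `alignments` (named by
#'   read id; each holds the forward-oriented original-base read and
#'   `base_at`, the read base aligned to every covered target position,
#'   `NA` at read gaps).
#' @export
align_reads <- function(reads, index, library = c("NONDIR", "DIR"),
                        min_identity = 0.80, min_aligned_length = 30L,
                        scoring = align_scoring()) {
  library <- match.arg(library)
  stopifnot(inherits(index, "converted_index"))
  n <- nrow(reads)
  if (n == 0L) {
    return(structure(list(summary = empty_align_summary(),
                          alignments = list()),
                     class = "amplicon_alignments"))
  }
  if (any(nchar(reads$sequence) == 0L)) {
    am_stop("ampliMeth_empty_read",
            "empty reads must be removed before alignment")
  }
  submat <- align_submat(scoring$match, scoring$mismatch)
  states <- strand_states(library)

  fwd <- toupper(reads$sequence)
  rc <- rev_comp(fwd)
  conv <- list(
    ct_fwd = Biostrings::DNAStringSet(ct_convert(fwd)),
    ct_rc  = Biostrings::DNAStringSet(ct_convert(rc)),
    ga_fwd = Biostrings::DNAStringSet(ga_convert(fwd)),
    ga_rc  = Biostrings::DNAStringSet(ga_convert(rc)))
  pattern_for <- function(st) {
    conv[[paste0(st$space, if (st$rc) "_rc" else "_fwd")]]
  }

  # score every (target x state) candidate for all reads at once
  cand <- expand.grid(target = names(index), state = seq_len(nrow(states)),
                      stringsAsFactors = FALSE)
  scores <- matrix(-Inf, n, nrow(cand))
  for (j in seq_len(nrow(cand))) {
    st <- states[cand$state[j], ]
    subject <- Biostrings::DNAString(index[[cand$target[j]]][[st$space]])
    scores[, j] <- Biostrings::pairwiseAlignment(
      pattern_for(st), subject, type = "global-local",
      substitutionMatrix = submat,
      gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension,
      scoreOnly = TRUE)
  }

  best_j <- max.col(scores, ties.method = "first")
  best_score <- scores[cbind(seq_len(n), best_j)]
  second <- vapply(seq_len(n), function(i) {
    if (ncol(scores) == 1L) -Inf else max(scores[i, -best_j[i]])
  }, 0)
  ambiguous <- is.finite(best_score) & (abs(best_score - second) < 1e-9)

  summary <- data.frame(read_id = reads$id,
                        status = ifelse(ambiguous, "ambiguous", "mapped"),
                        target_name = cand$target[best_j],
                        strand_label = states$label[cand$state[best_j]],
                        score = best_score, identity = NA_real_,
                        target_start = NA_integer_, target_end = NA_integer_,
                        stringsAsFactors = FALSE)

  # Full alignment of every winner, grouped by candidate. Score-tied reads
  # are only reported ambiguous if their best candidate would be accepted;
  # a tie between below-threshold candidates is plain unmapped.
  alignments <- vector("list", n)
  for (j in unique(best_j)) {
    rows <- which(best_j == j)
    st <- states[cand$state[j], ]
    entry <- index[[cand$target[j]]]
    subject <- Biostrings::DNAString(entry[[st$space]])
    aln <- Biostrings::pairwiseAlignment(
      pattern_for(st)[rows], subject, type = "global-local",
      substitutionMatrix = submat,
      gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    sub_start <- Biostrings::start(Biostrings::subject(aln))
    oriented <- if (st$rc) rc[rows] else fwd[rows]
    for (k in seq_along(rows)) {
      i <- rows[k]
      rec <- extract_alignment(ap[k], as_[k], sub_start[k], oriented[k])
      identity <- rec$n_same / rec$n_cols
      span <- rec$target_end - rec$target_start
      if (identity < min_identity || span < min_aligned_length) {
        summary$status[i] <- "unmapped"
        next
      }
      if (ambiguous[i]) next
      summary$identity[i] <- identity
      summary$target_start[i] <- rec$target_start
      summary$target_end[i] <- rec$target_end
      alignments[[i]] <- structure(
        list(read_id = reads$id[i], target_name = entry$name,
             strand_label = st$label, score = best_score[i],
             identity = identity,
             target_start = rec$target_start, target_end = rec$target_end,
             oriented_read = oriented[k], base_at = rec$base_at,
             cigar = rec$cigar),
        class = "amplicon_alignment")
    }
  }
  keep <- !vapply(alignments, is.null, TRUE)
  alignments <- alignments[keep]
  names(alignments) <- summary$read_id[keep]
  structure(list(summary = summary, alignments = alignments),
            class = "amplicon_alignments")
}

empty_align_summary <- function() {
  data.frame(read_id = character(), status = character(),
             target_name = character(), strand_label = character(),
             score = numeric(), identity = numeric(),
             target_start = integer(), target_end = integer(),
             stringsAsFactors = FALSE)
}

# Walk the two gapped alignment strings and record, for each covered target
# position, the ORIGINAL (unconverted) oriented read base, NA at read gaps.
extract_alignment <- function(gapped_pattern, gapped_subject, sub_start,
                              oriented_read) {
  p <- strsplit(gapped_pattern, "")[[1L]]
  s <- strsplit(gapped_subject, "")[[1L]]
  orig <- strsplit(oriented_read, "")[[1L]]
  n_cols <- length(p)
  rpos <- 0L
  tpos <- sub_start - 1L          # last consumed 1-based target position
  t0 <- sub_start - 1L            # 0-based target start of the alignment
  base_at <- character(0)
  ops <- character(n_cols)
  n_same <- 0L
  for (c in seq_len(n_cols)) {
    pg <- p[c] == "-"; sg <- s[c] == "-"
    if (!pg) rpos <- rpos + 1L
    if (!sg) {
      tpos <- tpos + 1L
      base_at[tpos - t0] <- if (pg) NA_character_ else orig[rpos]
    }
    ops[c] <- if (pg) "D" else if (sg) "I" else "M"
    if (!pg && !sg && p[c] == s[c]) n_same <- n_same + 1L
  }
  r <- rle(ops)
  list(target_start = t0, target_end = tpos,  # 0-based half-open
       base_at = base_at, n_cols = n_cols, n_same = n_same,
       cigar = paste0(r$lengths, r$values, collapse = ""))
}

#' Convenience single-read alignment
#'
#' @param read a single-row `bs_reads` data.frame (or list with `id`,
#'   `sequence`, `quality`).
#' @inheritParams align_reads
#' @return one row of the [align_reads()] summary, with the alignment
#'   record (if accepted) as attribute `"alignment"`.
#' @export
align_read <- function(read, index, library = c("NONDIR", "DIR"),
                       min_identity = 0.80, min_aligned_length = 30L,
                       scoring = align_scoring()) {
  read <- as.data.frame(read, stringsAsFactors = FALSE)
  res <- align_reads(read, index, library, min_identity,
                     min_aligned_length, scoring)
  out <- res$summary[1L, , drop = FALSE]
  attr(out, "alignment") <- if (length(res$alignments)) res$alignments[[1L]] else NULL
  out
}

#' Mapping and coverage statistics
#'
#' @param aln an `amplicon_alignments` object.
#' @param targets the `target_set` that was aligned against.
#' @return list with `mapped_fraction` (mapped / all reads), `status_counts`
#'   and `per_target` (data.frame: `target_name`, `n_reads`, `mean_depth`
#'   where depth is aligned target bases divided by target length).
#' @export
mapping_stats <- function(aln, targets) {
  s <- aln$summary
  status_counts <- c(mapped = sum(s$status == "mapped"),
                     ambiguous = sum(s$status == "ambiguous"),
                     unmapped = sum(s$status == "unmapped"))
  total <- nrow(s)
  per_target <- data.frame(
    target_name = targets$name,
    n_reads = vapply(targets$name, function(t) {
      sum(s$status == "mapped" & s$target_name == t)
    }, 0L),
    mean_depth = vapply(seq_len(nrow(targets)), function(i) {
      t <- targets$name[i]
      rows <- s$status == "mapped" & s$target_name == t
      sum(s$target_end[rows] - s$target_start[rows]) / target_length(targets[i, ])
    }, 0),
    stringsAsFactors = FALSE)
  rownames(per_target) <- NULL
  list(mapped_fraction = if (total == 0L) 0 else unname(status_counts["mapped"]) / total,
       status_counts = status_counts,
       per_target = per_target)
}

#' Write accepted alignments as SAM
#'
#' Minimal single-end SAM rendering of accepted alignments: flag 0 for
#' forward placement (OT/CTOB) and 16 for reverse (OB/CTOT); the bisulfite
#' strand label travels in the `XS` tag slot of a sidecar-style extra
#' column. Coordinates are 1-based target coordinates per the SAM standard.
#'
#' @param aln an `amplicon_alignments` object.
#' @param targets the aligned `target_set`.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, targets, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_len(nrow(targets))) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", targets$name[i],
                       target_length(targets[i, ])), con)
  }
  for (a in aln$alignments) {
    # SEQ is stored in forward target orientation; flag 16 marks reads whose
    # sequenced orientation was the reverse complement (OB/CTOT).
    flag <- if (a$strand_label %in% c("OB", "CTOT")) 16L else 0L
    writeLines(paste(a$read_id, flag, a$target_name, a$target_start + 1L,
                     255L, a$cigar, "*", 0L, 0L, a$oriented_read, "*",
                     paste0("XB:Z:", a$strand_label), sep = "\t"), con)
  }
  invisible(path)
}
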
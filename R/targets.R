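#' Parse an amplicon target file
#'
#' Reads a tab-separated target file with one amplicon region per line:
#' `name`, `chrom`, `start`, `end`, `strand` and optionally further
#' annotation columns (e.g. an array probe ID), which are carried through
#' verbatim. Coordinates are 1-based and fully closed, so the span length is
#' `end - start + 1`. Lines starting with `#` and blank lines are ignored.
#'
#' @param path path to the TSV target file.
#' @return A `target_set`: a data.frame with columns `name`, `chrom`,
#'   `start`, `end`, `strand` (normalized to `+`/`-`), `annotation`
#'   (extra columns joined by tabs, `NA` if none) and `sequence`
#'   (`NA` until [attach_sequences()] is called). Row order follows the file.
#' @seealso [attach_sequences()], [enumerate_cpg_sites()], [target_length()]
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("amp1\tchr1\t100\t199\t+", tf)
#' parse_target_file(tf)
parse_target_file <- function(path) {
  if (!file.exists(path)) {
    am_stop("ampliMeth_missing_file", "target file not found: %s", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  lines <- lines[nzchar(lines) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) return(empty_target_set())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 5L)) {
    am_stop("ampliMeth_bad_fields",
            "target file line %d has %d field(s); at least 5 required",
            which(nf < 5L)[1L], min(nf))
  }
  fields <- lapply(fields, trimws)
  name   <- vapply(fields, `[[`, "", 1L)
  chrom  <- vapply(fields, `[[`, "", 2L)
  start_s <- vapply(fields, `[[`, "", 3L)
  end_s   <- vapply(fields, `[[`, "", 4L)
  strand  <- vapply(fields, `[[`, "", 5L)
  annotation <- vapply(fields, function(f) {
    if (length(f) > 5L) paste(f[-(1:5)], collapse = "\t") else NA_character_
  }, "")

  if (anyNA(suppressWarnings(as.numeric(start_s))) ||
      anyNA(suppressWarnings(as.numeric(end_s))) ||
      any(as.numeric(start_s) != floor(as.numeric(start_s))) ||
      any(as.numeric(end_s) != floor(as.numeric(end_s)))) {
    am_stop("ampliMeth_bad_coordinates",
            "non-integer start/end coordinate in target file")
  }
  start <- as.integer(round(as.numeric(start_s)))
  end <- as.integer(round(as.numeric(end_s)))
  if (any(end < start)) {
    bad <- name[end < start][1L]
    am_stop("ampliMeth_bad_coordinates", "target '%s' has end < start", bad)
  }
  if (anyDuplicated(name)) {
    am_stop("ampliMeth_duplicate_name",
            "duplicate target name: %s", name[duplicated(name)][1L])
  }
  strand <- normalize_strand(strand)

  out <- data.frame(name = name, chrom = chrom, start = start, end = end,
                    strand = strand, annotation = annotation,
                    sequence = NA_character_, stringsAsFactors = FALSE)
  class(out) <- c("target_set", "data.frame")
  out
}

empty_target_set <- function() {
  out <- data.frame(name = character(), chrom = character(),
                    start = integer(), end = integer(),
                    strand = character(), annotation = character(),
                    sequence = character(), stringsAsFactors = FALSE)
  class(out) <- c("target_set", "data.frame")
  out
}

normalize_strand <- function(strand) {
  # Accepts ASCII +/- and the unicode minus that copy-pasted tables carry.
  std <- ifelse(strand %in% c("+", "plus", "1"), "+",
         ifelse(strand %in% c("-", "−", "minus", "-1"), "-", NA))
  if (anyNA(std)) {
    am_stop("ampliMeth_bad_strand",
            "unknown strand token: '%s'", strand[is.na(std)][1L])
  }
  std
}

#' Write a target set back to a target file
#'
#' Inverse of [parse_target_file()]; annotation columns are preserved.
#'
#' @param targets a `target_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_file <- function(targets, path) {
  lines <- vapply(seq_len(nrow(targets)), function(i) {
    base <- paste(targets$name[i], targets$chrom[i], targets$start[i],
                  targets$end[i], targets$strand[i], sep = "\t")
    if (!is.na(targets$annotation[i])) {
      base <- paste(base, targets$annotation[i], sep = "\t")
    }
    base
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Attach reference sequences to targets
#'
#' Resolves each target against a FASTA source. Two layouts are supported and
#' detected per target: genomic mode, where a FASTA record is named by the
#' target's chromosome and the 1-based closed span `[start, end]` is sliced
#' from it, and per-amplicon mode, where a record named by the target's name
#' holds exactly the amplicon sequence. The stored sequence is always the
#' forward-strand sequence; the target's `strand` column is metadata for the
#' strand filter and never triggers reverse complementation.
#'
#' @param targets a `target_set`.
#' @param reference path to a FASTA file, or a named character vector of
#'   sequences.
#' @return the `target_set` with the `sequence` column filled (uppercase).
#' @export
attach_sequences <- function(targets, reference) {
  if (is.character(reference) && length(reference) == 1L && is.null(names(reference))) {
    if (!file.exists(reference)) {
      am_stop("ampliMeth_missing_file", "reference FASTA not found: %s", reference)
    }
    fa <- Biostrings::readDNAStringSet(reference)
    seqs <- setNames(as.character(fa), sub("\\s.*$", "", names(fa)))
  } else {
    seqs <- as.character(reference)
  }
  seqs <- toupper(seqs)

  targets$sequence <- vapply(seq_len(nrow(targets)), function(i) {
    nm <- targets$name[i]; ch <- targets$chrom[i]
    st <- targets$start[i]; en <- targets$end[i]
    len <- en - st + 1L
    if (ch %in% names(seqs)) {
      contig <- seqs[[ch]]
      if (st < 1L || en > nchar(contig)) {
        am_stop("ampliMeth_span_out_of_bounds",
                "target '%s' span %d-%d outside contig '%s' (1-%d)",
                nm, st, en, ch, nchar(contig))
      }
      substr(contig, st, en)
    } else if (nm %in% names(seqs)) {
      amp <- seqs[[nm]]
      if (nchar(amp) != len) {
        am_stop("ampliMeth_bad_amplicon_record",
                "amplicon record '%s' has width %d but target length is %d",
                nm, nchar(amp), len)
      }
      amp
    } else {
      am_stop("ampliMeth_missing_contig",
              "neither contig '%s' nor amplicon record '%s' found in reference",
              ch, nm)
    }
  }, "")
  targets
}

#' Target span length in base pairs
#'
#' Under the 1-based fully-closed coordinate convention of the target file,
#' the length of a span is `end - start + 1`.
#'
#' @param target a `target_set` (or any data.frame with `start`/`end`).
#' @return integer vector of lengths, one per target.
#' @export
#' @examples
#' target_length(data.frame(start = 156627114, end = 156627680)) # 567
target_length <- function(target) {
  if (any(target$end < target$start)) {
    am_stop("ampliMeth_bad_coordinates", "end < start")
  }
  as.integer(target$end - target$start + 1L)
}

#' Enumerate CpG sites of a target
#'
#' Scans the attached forward-strand sequence left to right for `CG`
#' dinucleotides. `offset` is the 0-based position of the C within the target
#' sequence; `genome_pos` is its 1-based forward-strand genomic coordinate.
#' `CGCG` yields two sites (no merging of neighbours).
#'
#' @param target one row of a `target_set` with `sequence` attached.
#' @return data.frame with columns `target_name`, `offset`, `genome_pos`,
#'   ordered by increasing offset; zero rows if the sequence has no CpG.
#' @export
enumerate_cpg_sites <- function(target) {
  stopifnot(nrow(target) == 1L)
  seq <- target$sequence
  if (is.na(seq)) {
    am_stop("ampliMeth_no_sequence",
            "target '%s' has no attached sequence", target$name)
  }
  m <- gregexpr("CG", seq, fixed = TRUE)[[1L]]
  off <- if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  data.frame(target_name = rep(target$name, length(off)),
             offset = off,
             genome_pos = target$start + off,
             stringsAsFactors = FALSE)
}

#' Enumerate CpH cytosine positions of a target
#'
#' Positions carrying bisulfite-informative cytosines outside a CpG context,
#' on both strands of the forward sequence: a forward-strand `C` not followed
#' by `G` (`+` side) and a `G` not preceded by `C`, i.e. a bottom-strand
#' cytosine outside CpG context (`-` side).
#'
#' @param target one row of a `target_set` with `sequence` attached.
#' @return data.frame with columns `target_name`, `offset` (0-based position
#'   of the informative base), `genome_pos`, `strand`.
#' @export
enumerate_cph_sites <- function(target) {
  stopifnot(nrow(target) == 1L)
  seq <- target$sequence
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  plus <- which(ch == "C" & c(ch[-1L], "") != "G") - 1L
  minus <- which(ch == "G" & c("", ch[-n]) != "C") - 1L
  off <- c(plus, minus)
  strand <- c(rep("+", length(plus)), rep("-", length(minus)))
  o <- order(off)
  data.frame(target_name = rep(target$name, length(off)),
             offset = off[o], genome_pos = target$start + off[o],
             strand = strand[o], stringsAsFactors = FALSE)
}
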
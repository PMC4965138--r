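#' Size of the methylation-pattern space
#'
#' An amplicon with `n` CpG sites admits `2^n` read-level methylation
#' patterns, from fully unmethylated to fully methylated; with 3 CpGs there
#' are 8.
#'
#' @param n_cpgs number of CpG sites (>= 0).
#' @return `2^n_cpgs` as a numeric scalar.
#' @export
#' @examples
#' pattern_space_size(3)  # 8
pattern_space_size <- function(n_cpgs) {
  if (length(n_cpgs) != 1L || is.na(n_cpgs) || n_cpgs < 0 ||
      n_cpgs != floor(n_cpgs)) {
    am_stop("ampliMeth_bad_config", "n_cpgs must be a non-negative integer")
  }
  2^n_cpgs
}

#' Select reads spanning a target
#'
#' A read enters pattern analysis only if its aligned span covers at least
#' `p` percent of the target length. With the default `p = 100` this is the
#' set of reads covering the whole amplicon.
#'
#' @param aln an `amplicon_alignments` object.
#' @param target one row of a `target_set`.
#' @param p required span as a percentage in (0, 100].
#' @return character vector of read ids.
#' @export
select_spanning_reads <- function(aln, target, p = 100) {
  if (p <= 0 || p > 100) {
    am_stop("ampliMeth_bad_config", "span percentage must lie in (0, 100]")
  }
  s <- aln$summary
  L <- target_length(target)
  need <- p / 100 * L - 1e-9
  ok <- s$status == "mapped" & s$target_name == target$name &
    (s$target_end - s$target_start) >= need
  s$read_id[ok]
}

#' Extract and rank read-level methylation patterns
#'
#' Each spanning read contributes one pattern string over all CpG sites of
#' the target, `M` for methylated and `U` for unmethylated, in site order.
#' Reads missing any site (not covered, or `nocall` at any CpG) are
#' excluded entirely, since partial patterns would fragment the pattern
#' space. Patterns are aggregated by exact string and ranked by count
#' (descending), ties broken lexicographically.
#'
#' @param observations [call_read()]-layout observations of the spanning
#'   reads (e.g. [call_alignments()] subset to ids from
#'   [select_spanning_reads()]).
#' @param target one row of a `target_set` with sequence attached.
#' @return a `pattern_table` data.frame: `target_name`, `pattern`, `count`,
#'   `frequency` (over included reads). Zero rows if no read yields a
#'   complete pattern.
#' @export
extract_patterns <- function(observations, target) {
  sites <- enumerate_cpg_sites(target)
  n_sites <- nrow(sites)
  obs <- observations[observations$target_name == target$name, , drop = FALSE]
  patterns <- character(0)
  if (n_sites > 0L && nrow(obs) > 0L) {
    split_obs <- split(obs, obs$read_id)
    patterns <- vapply(split_obs, function(d) {
      st <- d$state[match(sites$offset, d$offset)]
      if (anyNA(st) || any(st == "nocall")) return(NA_character_)
      paste(ifelse(st == "methylated", "M", "U"), collapse = "")
    }, "")
    patterns <- patterns[!is.na(patterns)]
  }
  if (length(patterns) == 0L) {
    out <- data.frame(target_name = character(), pattern = character(),
                      count = integer(), frequency = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    cnt <- table(patterns)
    out <- data.frame(target_name = target$name, pattern = names(cnt),
                      count = as.integer(cnt),
                      frequency = as.integer(cnt) / sum(cnt),
                      stringsAsFactors = FALSE)
    out <- out[order(-out$count, out$pattern), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("pattern_table", "data.frame")
  out
}

#' Full per-sample pattern analysis for one target
#'
#' Convenience wrapper: selects spanning reads, restricts their
#' observations and extracts the ranked pattern table.
#'
#' @param aln an `amplicon_alignments` object.
#' @param observations CpG observations for the same alignments.
#' @param target one row of a `target_set`.
#' @param p span requirement in percent (see [select_spanning_reads()]).
#' @return a `pattern_table`.
#' @export
methylation_patterns <- function(aln, observations, target, p = 100) {
  ids <- select_spanning_reads(aln, target, p)
  obs <- observations[observations$read_id %in% ids, , drop = FALSE]
  extract_patterns(obs, target)
}

#' Compare methylation patterns across samples
#'
#' Builds, per target, the union of patterns observed in any sample and
#' tabulates each sample's frequency (0 where a pattern was not observed).
#' Rows are ordered by total count over all samples (descending), ties
#' lexicographic, giving the global rank order used in the text report.
#'
#' @param tables named list of `pattern_table`s, one per sample.
#' @return a `pattern_comparison` data.frame: `target_name`, `pattern`,
#'   `total_count`, then one `<sample>` frequency column per sample.
#' @export
compare_patterns <- function(tables) {
  if (length(tables) == 0L) am_stop("ampliMeth_bad_config", "no samples given")
  if (is.null(names(tables))) {
    names(tables) <- paste0("sample", seq_along(tables))
  }
  all_rows <- do.call(rbind, lapply(names(tables), function(s) {
    t <- tables[[s]]
    if (nrow(t) == 0L) return(NULL)
    cbind(t, sample = s, stringsAsFactors = FALSE)
  }))
  if (is.null(all_rows)) {
    out <- data.frame(target_name = character(), pattern = character(),
                      total_count = integer(), stringsAsFactors = FALSE)
    for (s in names(tables)) out[[s]] <- numeric(0)
    class(out) <- c("pattern_comparison", "data.frame")
    return(out)
  }
  key <- paste(all_rows$target_name, all_rows$pattern, sep = "\r")
  uk <- !duplicated(key)
  out <- data.frame(target_name = all_rows$target_name[uk],
                    pattern = all_rows$pattern[uk],
                    total_count = as.integer(
                      tapply(all_rows$count, key, sum)[key[uk]]),
                    stringsAsFactors = FALSE)
  for (s in names(tables)) {
    t <- tables[[s]]
    m <- match(paste(out$target_name, out$pattern, sep = "\r"),
               paste(t$target_name, t$pattern, sep = "\r"))
    f <- t$frequency[m]
    f[is.na(f)] <- 0
    out[[s]] <- f
  }
  out <- out[order(out$target_name, -out$total_count, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pattern_comparison", "data.frame")
  out
}

#' Render the cross-sample pattern comparison as a text document
#'
#' @param comparison a [compare_patterns()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(comparison, path) {
  con <- file(path, "w")
  on.exit(close(con))
  samples <- setdiff(colnames(comparison),
                     c("target_name", "pattern", "total_count"))
  for (t in unique(comparison$target_name)) {
    writeLines(sprintf("# target %s", t), con)
    writeLines(paste(c("pattern", "total_count", samples), collapse = "\t"), con)
    rows <- comparison[comparison$target_name == t, , drop = FALSE]
    for (i in seq_len(nrow(rows))) {
      writeLines(paste(c(rows$pattern[i], rows$total_count[i],
                         sprintf("%.4f", unlist(rows[i, samples]))),
                       collapse = "\t"), con)
    }
    writeLines("", con)
  }
  invisible(path)
}
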
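#' Minimum-coverage cutoff filter
#'
#' Flags every call whose total coverage (`n_meth + n_unmeth`) is strictly
#' below `r` reads. `r = 0` removes nothing.
#'
#' @param mat a `cpg_call_matrix`.
#' @param r minimum number of mapped reads required per CpG.
#' @return the matrix with `filtered`/`filter_reason` updated.
#' @export
min_coverage_filter <- function(mat, r = 10L) {
  if (r < 0L) am_stop("ampliMeth_bad_config", "min coverage must be >= 0")
  hit <- mat$coverage < r
  add_filter_flag(mat, hit, "min_coverage")
}

#' Mean-minus-one-SD coverage outlier filter
#'
#' Amplicon sequencing is expected to cover all CpGs of one sample/target
#' uniformly, so a site whose total coverage drops below the group's mean
#' coverage minus one standard deviation is an outlier. Within each
#' (sample, target, call strand) group the mean and sample (n-1) standard
#' deviation of the covered sites' coverages are computed over all such
#' sites — not just previously unfiltered ones, which keeps the stage
#' idempotent — and a site is flagged when its coverage is strictly below
#' `mean - sd`. Groups with fewer than two covered sites (SD undefined)
#' are never filtered; uniform groups have SD 0 and the strict inequality
#' keeps every site.
#'
#' @param mat a `cpg_call_matrix`.
#' @return the matrix with `filtered`/`filter_reason` updated.
#' @export
#' @examples
#' # coverages 100,100,100,10: mean 77.5, sd 45, threshold 32.5 -> flags the 10
mean_sd_filter <- function(mat) {
  hit <- logical(nrow(mat))
  grp <- paste(mat$sample, mat$target_name, mat$strand_of_call, sep = "\r")
  for (g in unique(grp)) {
    rows <- which(grp == g & mat$coverage > 0)
    if (length(rows) < 2L) next
    cov <- mat$coverage[rows]
    thr <- mean(cov) - sd(cov)
    hit[rows] <- cov < thr
  }
  add_filter_flag(mat, hit, "mean_sd")
}

#' Strand filter
#'
#' Removes calls whose strand differs from the strand recorded for the
#' target in the target file. Side-channel outputs keep both strands; only
#' the final table honours this filter.
#'
#' @param mat a `cpg_call_matrix`.
#' @param targets the `target_set` (provides the per-target strand).
#' @return the matrix with `filtered`/`filter_reason` updated.
#' @export
strand_filter <- function(mat, targets) {
  ts <- targets$strand[match(mat$target_name, targets$name)]
  if (anyNA(ts)) {
    am_stop("ampliMeth_missing_strand",
            "no target strand known for: %s",
            mat$target_name[is.na(ts)][1L])
  }
  add_filter_flag(mat, mat$strand_of_call != ts, "strand")
}

add_filter_flag <- function(mat, hit, reason) {
  # idempotent: re-applying the same filter never duplicates the reason
  already <- grepl(paste0("\\b", reason, "\\b"), mat$filter_reason)
  newly <- hit & !already
  mat$filtered <- mat$filtered | hit
  mat$filter_reason[newly] <- ifelse(nzchar(mat$filter_reason[newly]),
                                     paste(mat$filter_reason[newly], reason,
                                           sep = ";"),
                                     reason)
  mat
}

#' Apply the full filter stage
#'
#' Runs the three call-level filters in their narrative order: the
#' minimum-coverage cutoff, then the mean-minus-one-SD outlier filter
#' (computed on all covered sites of each group), then the strand filter.
#' Counts are never altered; rows are only flagged. The stage is
#' idempotent.
#'
#' @param mat a `cpg_call_matrix`.
#' @param targets the `target_set`.
#' @param min_reads_per_cpg the cutoff `r` (CLI `-r`).
#' @param apply_mean_sd whether to run the outlier filter.
#' @return the flagged matrix.
#' @export
apply_filters <- function(mat, targets, min_reads_per_cpg = 10L,
                          apply_mean_sd = TRUE) {
  mat <- min_coverage_filter(mat, min_reads_per_cpg)
  if (apply_mean_sd) mat <- mean_sd_filter(mat)
  strand_filter(mat, targets)
}

#' Write the filter diagnostics log
#'
#' One row per removed call with its coverage and the reason(s), so
#' filtered data remains auditable.
#'
#' @param mat a flagged `cpg_call_matrix`.
#' @param path output TSV path.
#' @return invisibly, the logged data.frame.
#' @export
write_filter_log <- function(mat, path) {
  log <- mat[mat$filtered,
             c("sample", "target_name", "genome_pos", "strand_of_call",
               "coverage", "filter_reason"), drop = FALSE]
  rownames(log) <- NULL
  write_tsv(log, path)
  invisible(log)
}
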
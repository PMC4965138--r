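#' Build the final cross-sample result table
#'
#' Aggregates the filtered call matrices of all samples into one wide
#' table: one row per (target, CpG genome position), annotation columns
#' first, then a triplet of columns per sample — methylated count,
#' unmethylated count and percent methylation. Cells removed by any filter
#' are `NA`. Row order follows the target file, then genomic position;
#' column order follows `sample_order` (default: order of appearance).
#'
#' @param mat a flagged `cpg_call_matrix` covering all samples.
#' @param targets the `target_set` (defines row order and annotation).
#' @param sample_order optional character vector of sample names.
#' @return a `result_table` data.frame with columns `target_name`, `chrom`,
#'   `genome_pos`, `strand`, then `<sample>.n_meth`, `<sample>.n_unmeth`,
#'   `<sample>.percent` per sample.
#' @export
build_result_table <- function(mat, targets, sample_order = NULL) {
  samples <- if (is.null(sample_order)) unique(mat$sample) else sample_order
  if (anyDuplicated(samples)) {
    am_stop("ampliMeth_duplicate_name", "duplicate sample name: %s",
            samples[duplicated(samples)][1L])
  }
  kept <- mat[!mat$filtered, , drop = FALSE]
  sites <- unique(mat[, c("target_name", "genome_pos")])
  sites <- sites[order(match(sites$target_name, targets$name),
                       sites$genome_pos), , drop = FALSE]
  out <- data.frame(
    target_name = sites$target_name,
    chrom = targets$chrom[match(sites$target_name, targets$name)],
    genome_pos = sites$genome_pos,
    strand = targets$strand[match(sites$target_name, targets$name)],
    stringsAsFactors = FALSE)
  rkey <- paste(out$target_name, out$genome_pos, sep = "\r")
  for (s in samples) {
    ks <- kept[kept$sample == s, , drop = FALSE]
    # after the strand filter a site has at most one surviving strand row;
    # if several survive (filters disabled), counts are summed
    nm <- tapply(ks$n_meth, paste(ks$target_name, ks$genome_pos, sep = "\r"), sum)
    nu <- tapply(ks$n_unmeth, paste(ks$target_name, ks$genome_pos, sep = "\r"), sum)
    m <- match(rkey, names(nm))
    n_meth <- as.integer(nm[m]); n_unmeth <- as.integer(nu[m])
    percent <- ifelse(!is.na(n_meth) & (n_meth + n_unmeth) > 0,
                      100 * n_meth / (n_meth + n_unmeth), NA_real_)
    out[[paste0(s, ".n_meth")]] <- n_meth
    out[[paste0(s, ".n_unmeth")]] <- n_unmeth
    out[[paste0(s, ".percent")]] <- percent
  }
  rownames(out) <- NULL
  class(out) <- c("result_table", "data.frame")
  out
}

#' Long view of a result table
#'
#' @param table a `result_table`.
#' @return data.frame with `sample`, `target_name`, `chrom`, `genome_pos`,
#'   `strand`, `n_meth`, `n_unmeth`, `percent`.
#' @export
result_table_long <- function(table) {
  samples <- unique(sub("\\.(n_meth|n_unmeth|percent)$", "",
                        grep("\\.percent$", colnames(table), value = TRUE)))
  do.call(rbind, lapply(samples, function(s) {
    data.frame(sample = s, target_name = table$target_name,
               chrom = table$chrom, genome_pos = table$genome_pos,
               strand = table$strand,
               n_meth = table[[paste0(s, ".n_meth")]],
               n_unmeth = table[[paste0(s, ".n_unmeth")]],
               percent = table[[paste0(s, ".percent")]],
               stringsAsFactors = FALSE)
  }))
}

#' Lollipop methylation diagram
#'
#' Draws the classic lollipop view of one target: one row of circles per
#' sample, one circle per CpG, with the fill shade proportional to percent
#' methylation (open = 0%, filled = 100%). Two x spacings are produced:
#' `equal` places CpGs at uniform intervals, `coordinate` at their true
#' chromosomal position — dense CpG clusters are legible in the former,
#' genomic context in the latter. Filtered (NA) cells are left blank.
#' Every figure writes a machine-readable sidecar TSV of the plotted
#' values, so plots are testable without image comparison.
#'
#' @param table a `result_table`.
#' @param target_name which target to draw.
#' @param path_prefix output prefix; files `<prefix>_<spacing>.png` and
#'   `<prefix>_<spacing>.tsv` are written per spacing.
#' @param spacing `"both"` (default), `"equal"` or `"coordinate"`.
#' @param sample_order optional sample ordering (top row first).
#' @param image_format `"png"` or `"svg"`; image rendering is skipped with
#'   a warning if no graphics device is available, the sidecar is always
#'   written.
#' @return invisibly, a named list of sidecar data.frames (`sample`,
#'   `genome_pos`, `x`, `percent`).
#' @export
lollipop <- function(table, target_name, path_prefix,
                     spacing = c("both", "equal", "coordinate"),
                     sample_order = NULL, image_format = "png") {
  spacing <- match.arg(spacing)
  spacings <- if (spacing == "both") c("equal", "coordinate") else spacing
  long <- result_table_long(table)
  long <- long[long$target_name == target_name, , drop = FALSE]
  if (nrow(long) == 0L) {
    am_stop("ampliMeth_bad_config", "target '%s' not in result table", target_name)
  }
  samples <- if (is.null(sample_order)) unique(long$sample) else sample_order
  long <- long[long$sample %in% samples, , drop = FALSE]
  pos <- sort(unique(long$genome_pos))
  out <- list()
  for (sp in spacings) {
    x <- if (sp == "equal") {
      match(long$genome_pos, pos)
    } else {
      long$genome_pos - min(pos) + 1L
    }
    side <- data.frame(sample = long$sample, genome_pos = long$genome_pos,
                       x = x, percent = long$percent,
                       stringsAsFactors = FALSE)
    side <- side[!is.na(side$percent), , drop = FALSE]
    rownames(side) <- NULL
    write_tsv(side, paste0(path_prefix, "_", sp, ".tsv"))
    out[[sp]] <- side
    img <- paste0(path_prefix, "_", sp, ".", image_format)
    plot_df <- side
    plot_df$sample <- factor(plot_df$sample, levels = rev(samples))
    p <- ggplot2::ggplot(plot_df,
                         ggplot2::aes(x = .data$x, y = .data$sample,
                                      fill = .data$percent)) +
      ggplot2::geom_point(shape = 21, size = 4, colour = "black") +
      ggplot2::scale_fill_gradient(low = "white", high = "black",
                                   limits = c(0, 100),
                                   name = "% methylation") +
      ggplot2::labs(title = sprintf("%s (%s spacing)", target_name, sp),
                    x = if (sp == "equal") "CpG index" else "position (bp)",
                    y = NULL) +
      ggplot2::theme_minimal()
    tryCatch(
      suppressMessages(ggplot2::ggsave(img, p, width = 8,
                                       height = 1 + 0.4 * length(samples),
                                       dpi = 120)),
      error = function(e) warning("lollipop image not rendered: ",
                                  conditionMessage(e)))
  }
  invisible(out)
}

#' Write run-level summary statistics
#'
#' Per-sample reads in / after QC / mapped / ambiguous / unmapped plus the
#' per-target mean depth, reconciling every input read.
#'
#' @param per_sample data.frame with columns `sample`, `reads_in`,
#'   `reads_after_qc`, `mapped`, `ambiguous`, `unmapped`.
#' @param per_target data.frame with `sample`, `target_name`, `n_reads`,
#'   `mean_depth`.
#' @param path output TSV path; per-target rows go to
#'   `<path>.targets.tsv`.
#' @return invisibly, `per_sample`.
#' @export
run_statistics <- function(per_sample, per_target, path) {
  per_sample$mapped_fraction <- ifelse(
    per_sample$reads_after_qc > 0,
    per_sample$mapped / per_sample$reads_after_qc, 0)
  write_tsv(per_sample, path)
  write_tsv(per_target, paste0(path, ".targets.tsv"))
  invisible(per_sample)
}

#' Concordance with an external per-CpG beta-value table
#'
#' Correlates sequencing percent methylation (divided by 100) against
#' array-style beta values in `[0, 1]`, matched by genome position, per
#' sample. Samples with fewer than two overlapping positions are reported
#' as `NA`. The summary medians use the standard even/odd median over
#' defined samples.
#'
#' @param table a `result_table`.
#' @param beta data.frame with columns `sample`, `genome_pos`, `beta`.
#' @return list with `per_sample` (data.frame: `sample`, `n_overlap`, `r`,
#'   `r_squared`), `median_r`, `median_r_squared`.
#' @export
array_concordance <- function(table, beta) {
  long <- result_table_long(table)
  samples <- unique(long$sample)
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    x <- long[long$sample == s & !is.na(long$percent), , drop = FALSE]
    b <- beta[beta$sample == s, , drop = FALSE]
    m <- merge(x[, c("genome_pos", "percent")],
               b[, c("genome_pos", "beta")], by = "genome_pos")
    m <- m[complete.cases(m), , drop = FALSE]
    r <- if (nrow(m) >= 2L) suppressWarnings(cor(m$percent / 100, m$beta)) else NA_real_
    data.frame(sample = s, n_overlap = nrow(m), r = r, r_squared = r^2,
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  ok <- !is.na(per_sample$r)
  list(per_sample = per_sample,
       median_r = if (any(ok)) median(per_sample$r[ok]) else NA_real_,
       median_r_squared = if (any(ok)) median(per_sample$r_squared[ok]) else NA_real_)
}
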
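#' Validate and complete a run configuration
#'
#' Applies the pipeline defaults to a raw argument list and validates every
#' field, mirroring the command-line flag set: target file (`-t`), library
#' (`-l`, default `NONDIR`), reference FASTA (`-g`), sequencing layout
#' (`-e`, default `SE`; `PE` inputs are processed as independent single-end
#' files with a warning), aligner (`-a`, `builtin` converted-space
#' aligner), minimum read length (`-m`, default 0), minimum 3' quality
#' (`-q`, default 20), pattern span percentage (`-p`, default 100),
#' minimum reads per CpG (`-r`, default 10), lollipop sample order (`-s`),
#' output directory (`-o`) and the input FASTQ files (or a directory,
#' `-d`).
#'
#' @param target_file path to the target TSV.
#' @param reference path to the reference FASTA (genomic or per-amplicon).
#' @param fastq_files character vector of FASTQ paths; sample names are the
#'   file basenames without extension.
#' @param output_dir run directory to create.
#' @param library `"NONDIR"` or `"DIR"`.
#' @param seq_layout `"SE"` or `"PE"`.
#' @param aligner only `"builtin"` is supported; the external mappers of
#'   other toolchains are not wrapped.
#' @param min_read_length minimum read length after trimming (`-m`).
#' @param min_3prime_quality phred threshold for 3' clipping (`-q`).
#' @param pattern_span_percent span requirement for pattern analysis (`-p`).
#' @param min_reads_per_cpg coverage cutoff (`-r`).
#' @param lollipop_sample_order optional sample ordering (`-s`).
#' @param fastq_dir optional directory scanned for `*.fastq`/`*.fq` (`-d`).
#' @return a validated `run_config` list.
#' @export
validate_config <- function(target_file, reference, fastq_files = character(),
                            output_dir,
                            library = "NONDIR", seq_layout = "SE",
                            aligner = "builtin",
                            min_read_length = 0L, min_3prime_quality = 20L,
                            pattern_span_percent = 100,
                            min_reads_per_cpg = 10L,
                            lollipop_sample_order = NULL,
                            fastq_dir = NULL) {
  if (!file.exists(target_file)) {
    am_stop("ampliMeth_missing_file", "target file not found: %s", target_file)
  }
  if (!file.exists(reference)) {
    am_stop("ampliMeth_missing_file", "reference not found: %s", reference)
  }
  if (!is.null(fastq_dir)) {
    fastq_files <- c(fastq_files,
                     list.files(fastq_dir, pattern = "\\.(fastq|fq)$",
                                full.names = TRUE))
  }
  if (length(fastq_files) == 0L) {
    am_stop("ampliMeth_no_input", "no input FASTQ files given")
  }
  missing <- fastq_files[!file.exists(fastq_files)]
  if (length(missing) > 0L) {
    am_stop("ampliMeth_missing_file", "FASTQ not found: %s", missing[1L])
  }
  if (!library %in% c("NONDIR", "DIR")) {
    am_stop("ampliMeth_bad_config", "library must be DIR or NONDIR")
  }
  if (!seq_layout %in% c("SE", "PE")) {
    am_stop("ampliMeth_bad_config", "seq_layout must be SE or PE")
  }
  if (seq_layout == "PE") {
    warning("PE layout: mates are processed as independent single-end files")
  }
  if (!identical(aligner, "builtin")) {
    am_stop("ampliMeth_bad_config",
            "aligner '%s' is not supported; only 'builtin' is available",
            aligner)
  }
  if (min_read_length < 0) am_stop("ampliMeth_bad_config", "-m must be >= 0")
  if (min_3prime_quality < 0) am_stop("ampliMeth_bad_config", "-q must be >= 0")
  if (pattern_span_percent <= 0 || pattern_span_percent > 100) {
    am_stop("ampliMeth_bad_config", "-p must lie in (0, 100]")
  }
  if (min_reads_per_cpg < 0) am_stop("ampliMeth_bad_config", "-r must be >= 0")
  samples <- sub("\\.(fastq|fq)$", "", basename(fastq_files))
  if (anyDuplicated(samples)) {
    am_stop("ampliMeth_duplicate_name", "duplicate sample name: %s",
            samples[duplicated(samples)][1L])
  }
  structure(list(target_file = target_file, reference = reference,
                 fastq_files = setNames(fastq_files, samples),
                 output_dir = output_dir, library = library,
                 seq_layout = seq_layout, aligner = aligner,
                 min_read_length = as.integer(min_read_length),
                 min_3prime_quality = as.integer(min_3prime_quality),
                 pattern_span_percent = pattern_span_percent,
                 min_reads_per_cpg = as.integer(min_reads_per_cpg),
                 lollipop_sample_order = lollipop_sample_order),
            class = "run_config")
}

#' Run the complete amplicon bisulfite analysis pipeline
#'
#' Orchestrates all stages on every sample: FASTQ QC (3' quality clipping,
#' minimum-length filter, before/after report), converted-space alignment,
#' per-CpG methylation calling with CpH and strand-specific side files,
#' the three call filters, methylation-pattern extraction and cross-sample
#' comparison, and the final result table with lollipop diagrams and run
#' statistics. Outputs are organized under `output_dir` in `qc/`, `align/`,
#' `calls/`, `filters/`, `patterns/` and `report/`, plus a `run_log.txt`
#' echoing every parameter. The run is fully deterministic for fixed
#' inputs.
#'
#' @param config a [validate_config()] result.
#' @return invisibly, a list with the main in-memory results:
#'   `result_table`, `call_matrix`, `pattern_comparison`, `stats`,
#'   `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  sub <- function(d) {
    p <- file.path(out, d)
    dir.create(p, showWarnings = FALSE, recursive = TRUE)
    p
  }
  dirs <- lapply(c("qc", "align", "calls", "filters", "patterns", "report"), sub)
  names(dirs) <- c("qc", "align", "calls", "filters", "patterns", "report")

  targets <- parse_target_file(config$target_file)
  if (nrow(targets) == 0L) {
    am_stop("ampliMeth_bad_config", "target file contains no targets")
  }
  targets <- attach_sequences(targets, config$reference)
  index <- build_converted_index(targets)
  samples <- names(config$fastq_files)
  min_aln_len <- if (config$min_read_length > 0L) config$min_read_length else 30L

  all_obs <- list(); all_cph <- list(); pattern_tabs <- list()
  per_sample_stats <- list(); per_target_stats <- list()
  for (s in samples) {
    reads <- read_fastq(config$fastq_files[[s]])
    before <- qc_summary(reads)
    reads <- trim_3prime(reads, config$min_3prime_quality)
    reads <- filter_min_length(reads, config$min_read_length)
    reads <- drop_empty_reads(reads)
    after <- qc_summary(reads)
    qc_report(before, after, file.path(dirs$qc, paste0(s, "_qc.tsv")))
    write_fastq(reads, file.path(dirs$qc, paste0(s, "_trimmed.fastq")))

    aln <- align_reads(reads, index, library = config$library,
                       min_aligned_length = min_aln_len)
    write_tsv(aln$summary, file.path(dirs$align, paste0(s, "_alignments.tsv")))
    write_sam(aln, targets, file.path(dirs$align, paste0(s, ".sam")))
    st <- mapping_stats(aln, targets)

    obs <- call_alignments(aln, index, "cpg")
    cph <- call_alignments(aln, index, "cph")
    obs$sample <- rep(s, nrow(obs)); cph$sample <- rep(s, nrow(cph))
    all_obs[[s]] <- obs; all_cph[[s]] <- cph

    mat_s <- accumulate(obs, targets, samples = s)
    write_bedgraph(mat_s, targets,
                   file.path(dirs$calls, paste0(s, "_cpg.bedGraph")))
    write_tsv(mat_s[mat_s$strand_of_call == "-", , drop = FALSE],
              file.path(dirs$calls, paste0(s, "_minus_strand.tsv")))
    cph_mat <- if (nrow(cph) > 0L) {
      agg <- aggregate(cbind(methylated = state == "methylated",
                             unmethylated = state == "unmethylated") ~
                         target_name + genome_pos + strand_of_call,
                       data = cph, FUN = sum)
      agg[order(agg$target_name, agg$genome_pos), , drop = FALSE]
    } else {
      data.frame(target_name = character(), genome_pos = integer(),
                 strand_of_call = character(), methylated = integer(),
                 unmethylated = integer())
    }
    write_tsv(cph_mat, file.path(dirs$calls, paste0(s, "_cph.tsv")))

    tabs <- lapply(seq_len(nrow(targets)), function(i) {
      methylation_patterns(aln, obs, targets[i, , drop = FALSE],
                           p = config$pattern_span_percent)
    })
    tab <- do.call(rbind, tabs)
    class(tab) <- c("pattern_table", "data.frame")
    write_tsv(tab, file.path(dirs$patterns, paste0(s, "_patterns.tsv")))
    pattern_tabs[[s]] <- tab

    per_sample_stats[[s]] <- data.frame(
      sample = s, reads_in = before$read_count,
      reads_after_qc = after$read_count,
      mapped = unname(st$status_counts["mapped"]),
      ambiguous = unname(st$status_counts["ambiguous"]),
      unmapped = unname(st$status_counts["unmapped"]),
      stringsAsFactors = FALSE)
    pt <- st$per_target; pt$sample <- rep(s, nrow(pt))
    per_target_stats[[s]] <- pt[, c("sample", "target_name", "n_reads",
                                    "mean_depth")]
  }

  obs_all <- do.call(rbind, all_obs)
  mat <- accumulate(obs_all, targets, samples = samples)
  mat <- apply_filters(mat, targets,
                       min_reads_per_cpg = config$min_reads_per_cpg)
  write_tsv(mat, file.path(dirs$filters, "call_matrix.tsv"))
  write_filter_log(mat, file.path(dirs$filters, "filter_log.tsv"))

  comparison <- compare_patterns(pattern_tabs)
  write_tsv(comparison, file.path(dirs$patterns, "pattern_comparison.tsv"))
  write_pattern_report(comparison,
                       file.path(dirs$patterns, "pattern_comparison.txt"))

  table <- build_result_table(mat, targets,
                              sample_order = config$lollipop_sample_order)
  write_tsv(table, file.path(dirs$report, "final_table.tsv"))
  long <- result_table_long(table)
  for (t in targets$name) {
    rows <- long[long$target_name == t, , drop = FALSE]
    if (any(!is.na(rows$percent))) {
      lollipop(table, t, file.path(dirs$report, paste0("lollipop_", t)),
               sample_order = config$lollipop_sample_order)
    }
  }
  stats <- run_statistics(do.call(rbind, per_sample_stats),
                          do.call(rbind, per_target_stats),
                          file.path(dirs$report, "run_statistics.tsv"))

  log_path <- file.path(out, "run_log.txt")
  writeLines(c(
    sprintf("ampliMeth %s", as.character(utils::packageVersion("ampliMeth"))),
    sprintf("date\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("target_file\t%s", config$target_file),
    sprintf("reference\t%s", config$reference),
    sprintf("library\t%s", config$library),
    sprintf("seq_layout\t%s", config$seq_layout),
    sprintf("aligner\t%s", config$aligner),
    sprintf("min_read_length\t%d", config$min_read_length),
    sprintf("min_3prime_quality\t%d", config$min_3prime_quality),
    sprintf("pattern_span_percent\t%s", config$pattern_span_percent),
    sprintf("min_reads_per_cpg\t%d", config$min_reads_per_cpg),
    sprintf("samples\t%s", paste(names(config$fastq_files), collapse = ",")),
    sprintf("fastq\t%s", paste(config$fastq_files, collapse = ","))),
    log_path)

  invisible(list(result_table = table, call_matrix = mat,
                 pattern_comparison = comparison, stats = stats,
                 output_dir = out))
}
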
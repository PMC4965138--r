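#' Simulation configuration for synthetic bisulfite amplicon reads
#'
#' Bundles every knob of the read simulator. Defaults describe a realistic
#' semiconductor-sequencer amplicon run: roughly 380 reads per amplicon,
#' 99% bisulfite conversion, 1% substitution errors, homopolymer-scaled
#' indel errors and a quality profile that decays over the 3' tail.
#'
#' @param per_cpg_methylation either a single probability, a vector of
#'   per-CpG probabilities (recycled/indexed by site order), or a pattern
#'   mixture given as `list(patterns = c("MMU", ...), weights = c(...))`
#'   where each pattern string covers all CpGs of the target.
#' @param conversion_efficiency probability that an unmethylated cytosine is
#'   converted to thymine during bisulfite treatment.
#' @param library `"NONDIR"` (reads arise uniformly from all four bisulfite
#'   strands OT/OB/CTOT/CTOB) or `"DIR"` (OT/OB only).
#' @param n_reads number of reads to simulate per target.
#' @param substitution_rate per-base probability of a substitution error.
#' @param homopolymer_indel_rate base rate of the homopolymer error model:
#'   each maximal homopolymer run of length `L >= 2` suffers a one-base
#'   insertion or deletion (equal odds) with probability
#'   `min(0.5, rate * (L - 1))`.
#' @param read_span fraction of the target covered by each read: `1.0` for
#'   full-span amplicon reads, or a length-2 vector giving a uniform range
#'   of fractions; partial reads are placed uniformly within the target.
#' @param quality_profile `"decay"` for a Q35 plateau falling linearly to
#'   Q12 over the final 15% of the read, or `"flat"` for constant Q35.
#' @param seed integer seed; the same seed and configuration always
#'   reproduce identical reads.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(per_cpg_methylation = 0.5,
                       conversion_efficiency = 0.99,
                       library = c("NONDIR", "DIR"),
                       n_reads = 380L,
                       substitution_rate = 0.01,
                       homopolymer_indel_rate = 0.01,
                       read_span = 1.0,
                       quality_profile = c("decay", "flat"),
                       seed = 1L) {
  library <- match.arg(library)
  quality_profile <- match.arg(quality_profile)
  probs <- c(conversion_efficiency, substitution_rate, homopolymer_indel_rate)
  if (is.numeric(per_cpg_methylation)) probs <- c(probs, per_cpg_methylation)
  if (any(probs < 0 | probs > 1)) {
    am_stop("ampliMeth_bad_config", "probabilities must lie in [0, 1]")
  }
  if (n_reads < 0) am_stop("ampliMeth_bad_config", "n_reads must be >= 0")
  if (any(read_span <= 0 | read_span > 1)) {
    am_stop("ampliMeth_bad_config", "read_span fractions must lie in (0, 1]")
  }
  structure(list(per_cpg_methylation = per_cpg_methylation,
                 conversion_efficiency = conversion_efficiency,
                 library = library,
                 n_reads = as.integer(n_reads),
                 substitution_rate = substitution_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 read_span = read_span,
                 quality_profile = quality_profile,
                 seed = seed),
            class = "sim_config")
}

#' In-silico bisulfite conversion of one molecule
#'
#' Applies the bisulfite chemistry to a forward-strand target sequence:
#' unmethylated cytosines deaminate and are read as thymine, methylated
#' cytosines are protected. For the original-top channel (`OT`, `CTOT`) the
#' convertible bases are the forward-strand Cs; for the original-bottom
#' channel (`OB`, `CTOB`) they are the bottom-strand Cs, which appear as
#' G-to-A changes in forward coordinates. The result is always returned in
#' forward target coordinates (a `CTOT`/`CTOB` product is identical to the
#' corresponding `OT`/`OB` product there and differs only in sequencing
#' orientation, which [simulate_reads()] applies).
#'
#' @param sequence forward-strand DNA string.
#' @param cpg_states methylation state per CpG site of `sequence`, in site
#'   order: logical (`TRUE` = methylated) or characters `"M"`/`"U"`.
#' @param conversion_efficiency probability that an unprotected cytosine is
#'   converted.
#' @param strand_origin one of `"OT"`, `"OB"`, `"CTOT"`, `"CTOB"`.
#' @return the converted sequence in forward coordinates.
#' @export
#' @examples
#' bisulfite_convert("ACGTCA", cpg_states = TRUE, strand_origin = "OT")  # "ACGTTA"
#' bisulfite_convert("ACGTCA", cpg_states = FALSE, strand_origin = "OT") # "ATGTTA"
bisulfite_convert <- function(sequence, cpg_states,
                              conversion_efficiency = 1.0,
                              strand_origin = c("OT", "OB", "CTOT", "CTOB")) {
  strand_origin <- match.arg(strand_origin)
  if (is.character(cpg_states)) cpg_states <- cpg_states == "M"
  ch <- strsplit(sequence, "")[[1L]]
  m <- gregexpr("CG", sequence, fixed = TRUE)[[1L]]
  cpg_c <- if (m[1L] == -1L) integer(0) else as.integer(m)  # 1-based C position
  if (length(cpg_states) == 1L) cpg_states <- rep(cpg_states, length(cpg_c))
  if (length(cpg_states) != length(cpg_c)) {
    am_stop("ampliMeth_bad_config",
            "cpg_states has length %d but sequence has %d CpG sites",
            length(cpg_states), length(cpg_c))
  }
  if (strand_origin %in% c("OT", "CTOT")) {
    convertible <- which(ch == "C")
    protected <- cpg_c[cpg_states]
    to <- "T"
  } else {
    convertible <- which(ch == "G")
    protected <- cpg_c[cpg_states] + 1L  # bottom-strand C pairs the CpG G
    to <- "A"
  }
  candidates <- setdiff(convertible, protected)
  if (length(candidates) > 0L && conversion_efficiency > 0) {
    hit <- candidates[runif(length(candidates)) < conversion_efficiency]
    ch[hit] <- to
  }
  paste(ch, collapse = "")
}

# Quality string for a read of length n under the configured profile.
sim_qualities <- function(n, profile) {
  if (n == 0L) return("")
  q <- rep(35L, n)
  if (profile == "decay") {
    tail_len <- ceiling(0.15 * n)
    if (tail_len > 0L) {
      idx <- (n - tail_len + 1L):n
      q[idx] <- as.integer(round(35 - (35 - 12) * seq_along(idx) / tail_len))
    }
  }
  int_to_phred(q)
}

# One-base insertions/deletions on maximal homopolymer runs of length >= 2.
apply_homopolymer_indels <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) < 2L) return(list(seq = seq, n_indel = 0L))
  r <- rle(strsplit(seq, "")[[1L]])
  n_indel <- 0L
  for (i in seq_along(r$lengths)) {
    L <- r$lengths[i]
    if (L >= 2L && runif(1) < min(0.5, rate * (L - 1))) {
      r$lengths[i] <- if (runif(1) < 0.5) L + 1L else L - 1L
      n_indel <- n_indel + 1L
    }
  }
  list(seq = paste(inverse.rle(r), collapse = ""), n_indel = n_indel)
}

apply_substitutions <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0L) return(list(seq = seq, n_sub = 0L))
  ch <- strsplit(seq, "")[[1L]]
  hit <- which(runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit))
}

draw_cpg_states <- function(config, n_sites) {
  p <- config$per_cpg_methylation
  if (is.list(p)) {
    if (any(nchar(p$patterns) != n_sites)) {
      am_stop("ampliMeth_bad_config",
              "pattern strings must cover all %d CpG sites", n_sites)
    }
    k <- sample.int(length(p$patterns), 1L, prob = p$weights)
    strsplit(p$patterns[k], "")[[1L]] == "M"
  } else {
    if (length(p) == 1L) p <- rep(p, n_sites)
    runif(n_sites) < p
  }
}

#' Simulate bisulfite amplicon reads with known truth
#'
#' Generates `n_reads` single-end reads from one amplicon target: a strand
#' origin is drawn (uniform over OT/OB/CTOT/CTOB for non-directional
#' libraries, OT/OB for directional), per-CpG methylation states are drawn
#' from the configured model, the molecule is bisulfite-converted, the read
#' span is cut out and oriented as the sequencer would deliver it, and
#' substitution plus homopolymer indel errors are applied. Identical seed
#' and configuration yield identical output.
#'
#' @param target one row of a `target_set` with `sequence` attached.
#' @param config a [sim_config()].
#' @return list with elements `reads` (a `bs_reads` data.frame: `id`,
#'   `sequence`, `quality` in phred+33) and `truth` (data.frame: `read_id`,
#'   `target_name`, `strand_origin`, `span_start`/`span_end` 1-based closed
#'   on the target, `states` as an M/U string over the CpG sites covered by
#'   the span, `n_sub`, `n_indel`).
#' @export
simulate_reads <- function(target, config) {
  stopifnot(inherits(config, "sim_config"), nrow(target) == 1L)
  seq <- target$sequence
  if (is.na(seq)) am_stop("ampliMeth_no_sequence", "target has no sequence")
  L <- nchar(seq)
  sites <- enumerate_cpg_sites(target)
  n_sites <- nrow(sites)
  strands <- if (config$library == "NONDIR") c("OT", "OB", "CTOT", "CTOB") else c("OT", "OB")

  with_seed(config$seed, {
    n <- config$n_reads
    ids <- if (n == 0L) character(0) else
      sprintf("%s_read%05d", target$name, seq_len(n))
    seqs <- character(n); quals <- character(n)
    t_strand <- character(n); t_states <- character(n)
    span_start <- integer(n); span_end <- integer(n)
    n_sub <- integer(n); n_indel <- integer(n)

    for (i in seq_len(n)) {
      strand <- sample(strands, 1L)
      f <- if (length(config$read_span) == 2L) {
        runif(1, config$read_span[1L], config$read_span[2L])
      } else config$read_span
      span_len <- max(1L, min(L, as.integer(round(f * L))))
      s0 <- if (span_len >= L) 1L else sample.int(L - span_len + 1L, 1L)
      s1 <- s0 + span_len - 1L

      states <- draw_cpg_states(config, n_sites)
      covered <- which(sites$offset + 1L >= s0 & sites$offset + 2L <= s1)

      mol <- bisulfite_convert(seq, states, config$conversion_efficiency, strand)
      frag <- substr(mol, s0, s1)
      if (strand %in% c("OB", "CTOT")) frag <- rev_comp(frag)
      sub <- apply_substitutions(frag, config$substitution_rate)
      ind <- apply_homopolymer_indels(sub$seq, config$homopolymer_indel_rate)

      seqs[i] <- ind$seq
      quals[i] <- sim_qualities(nchar(ind$seq), config$quality_profile)
      t_strand[i] <- strand
      t_states[i] <- paste(ifelse(states[covered], "M", "U"), collapse = "")
      span_start[i] <- s0; span_end[i] <- s1
      n_sub[i] <- sub$n_sub; n_indel[i] <- ind$n_indel
    }

    reads <- data.frame(id = ids, sequence = seqs, quality = quals,
                        stringsAsFactors = FALSE)
    class(reads) <- c("bs_reads", "data.frame")
    truth <- data.frame(read_id = ids,
                        target_name = rep(target$name, n),
                        strand_origin = t_strand,
                        span_start = span_start, span_end = span_end,
                        states = t_states, n_sub = n_sub, n_indel = n_indel,
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}

#' Generate a random amplicon target with planted CpG sites
#'
#' Builds a synthetic forward-strand amplicon whose background sequence is
#' CpG-free and plants exactly `n_cpg` CG dinucleotides at evenly spread
#' positions, so the CpG complement of the target is fully controlled.
#'
#' @param name target name.
#' @param length_bp amplicon length in bp.
#' @param n_cpg number of CpG sites to plant.
#' @param chrom chromosome label for the synthetic coordinate system.
#' @param start 1-based genomic start.
#' @param strand reported target strand.
#' @param seed integer seed.
#' @return a single-row `target_set` with `sequence` attached.
#' @export
random_target <- function(name = "amp1", length_bp = 300L, n_cpg = 6L,
                          chrom = "chrS", start = 1001L, strand = "+",
                          seed = 1L) {
  if (length_bp < 2L * n_cpg + 2L) {
    am_stop("ampliMeth_bad_config", "length_bp too short for %d CpG sites", n_cpg)
  }
  seq <- with_seed(seed, {
    ch <- sample(c("A", "C", "G", "T"), length_bp, replace = TRUE)
    # knock out accidental CGs so planted sites are the only ones
    repeat {
      cg <- which(ch == "C" & c(ch[-1L], "") == "G")
      if (length(cg) == 0L) break
      ch[cg] <- sample(c("A", "T"), length(cg), replace = TRUE)
    }
    if (n_cpg > 0L) {
      pos <- as.integer(round(seq(2, length_bp - 2L, length.out = n_cpg)))
      # keep planted sites non-adjacent to each other
      ch[pos] <- "C"; ch[pos + 1L] <- "G"
      ch[pos - 1L][ch[pos - 1L] == "C"] <- "A"
      ch[pos + 2L][ch[pos + 2L] == "G"] <- "T"
      repeat {
        cg <- which(ch == "C" & c(ch[-1L], "") == "G")
        extra <- setdiff(cg, pos)
        if (length(extra) == 0L) break
        ch[extra] <- "A"
      }
    }
    paste(ch, collapse = "")
  })
  out <- data.frame(name = name, chrom = chrom, start = as.integer(start),
                    end = as.integer(start + length_bp - 1L),
                    strand = strand, annotation = NA_character_,
                    sequence = seq, stringsAsFactors = FALSE)
  class(out) <- c("target_set", "data.frame")
  out
}

#' Write a complete synthetic run fixture to disk
#'
#' Materializes a multi-sample, multi-target simulated run: the target file,
#' a per-amplicon reference FASTA, one FASTQ per sample and a truth TSV
#' enumerating every simulated read with its sample, target, strand origin
#' and methylation states. Per-sample, per-target seeds are derived
#' deterministically from each sample's configured seed, so rerunning with
#' the same inputs reproduces byte-identical files.
#'
#' @param targets a `target_set` with sequences attached.
#' @param configs named list of [sim_config()] objects, one per sample; the
#'   names become sample names and FASTQ basenames.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with paths: `target_file`, `reference`,
#'   `fastq` (named per sample), `truth`.
#' @export
write_run_fixture <- function(targets, configs, out_dir) {
  if (is.null(names(configs)) || any(!nzchar(names(configs)))) {
    am_stop("ampliMeth_bad_config", "configs must be a named list (sample names)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) {
    am_stop("ampliMeth_unwritable", "cannot create output directory: %s", out_dir)
  }
  target_file <- file.path(out_dir, "targets.tsv")
  write_target_file(targets, target_file)
  ref_path <- file.path(out_dir, "reference.fasta")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(setNames(targets$sequence, targets$name)), ref_path)

  fastq_paths <- character(0)
  truth_all <- list()
  for (si in seq_along(configs)) {
    sample <- names(configs)[si]
    cfg <- configs[[si]]
    reads_s <- list(); truth_s <- list()
    for (ti in seq_len(nrow(targets))) {
      cfg_t <- cfg
      cfg_t$seed <- derive_seed(cfg$seed, si * 10000L + ti)
      sim <- simulate_reads(targets[ti, , drop = FALSE], cfg_t)
      if (nrow(sim$reads) > 0L) {
        sim$reads$id <- paste0(sample, "_", sim$reads$id)
        sim$truth$read_id <- paste0(sample, "_", sim$truth$read_id)
      }
      reads_s[[ti]] <- sim$reads
      sim$truth$sample <- rep(sample, nrow(sim$truth))
      truth_s[[ti]] <- sim$truth
    }
    reads <- do.call(rbind, reads_s)
    class(reads) <- c("bs_reads", "data.frame")
    fq <- file.path(out_dir, paste0(sample, ".fastq"))
    write_fastq(reads, fq)
    fastq_paths[sample] <- fq
    truth_all[[si]] <- do.call(rbind, truth_s)
  }
  truth <- do.call(rbind, truth_all)
  truth <- truth[, c("sample", "read_id", "target_name", "strand_origin",
                     "span_start", "span_end", "states", "n_sub", "n_indel")]
  truth_path <- file.path(out_dir, "truth.tsv")
  write_tsv(truth, truth_path)
  invisible(list(target_file = target_file, reference = ref_path,
                 fastq = fastq_paths, truth = truth_path))
}
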
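test_that("per-read calling follows the conversion chemistry on both strands", {
  target <- mk_target("AACGTT", start = 101L)
  entry <- build_converted_index(target)[["amp1"]]

  # OT read retaining C at the CpG -> methylated on '+'
  obs <- call_read(mk_alignment("AACGTT", strand_label = "OT"), entry)
  expect_equal(obs$state, "methylated")
  expect_equal(obs$strand_of_call, "+")
  expect_equal(obs$genome_pos, 103L)

  # OT read with converted T -> unmethylated
  obs <- call_read(mk_alignment("AATGTT", strand_label = "OT"), entry)
  expect_equal(obs$state, "unmethylated")

  # OB read reports through the G of the CpG on '-'
  obs <- call_read(mk_alignment("AACGTT", strand_label = "OB"), entry)
  expect_equal(obs$state, "methylated")
  expect_equal(obs$strand_of_call, "-")
  obs <- call_read(mk_alignment("AACATT", strand_label = "OB"), entry)
  expect_equal(obs$state, "unmethylated")

  # a gap over the informative base is a nocall
  a <- mk_alignment("AACGTT", strand_label = "OT")
  a$base_at[3] <- NA
  expect_equal(call_read(a, entry)$state, "nocall")
  # a non-concordant base is a nocall too
  a2 <- mk_alignment("AAGGTT", strand_label = "OT")
  expect_equal(call_read(a2, entry)$state, "nocall")
})

test_that("only CpGs whose informative base is covered are reported", {
  target <- mk_target("ACGTACGT")
  entry <- build_converted_index(target)[["amp1"]]
  # read covers offsets 0..3 only: second CpG (offset 5) is out of span
  a <- mk_alignment("ACGT", strand_label = "OT")
  expect_equal(call_read(a, entry)$offset, 1L)
  # on '-' the informative base of CpG at offset 1 is offset 2
  a2 <- mk_alignment("CG", strand_label = "OB", target_start = 2L)
  expect_equal(nrow(call_read(a2, entry)), 1L)
})

test_that("accumulation counts, percentages and the complete site grid", {
  target <- mk_target("AACGTT")
  obs <- do.call(rbind, lapply(1:10, function(i) {
    data.frame(read_id = paste0("r", i), target_name = "amp1", offset = 2L,
               genome_pos = 103L, state = if (i <= 7) "methylated" else "unmethylated",
               strand_of_call = "+", stringsAsFactors = FALSE)
  }))
  mat <- accumulate(obs, target)
  plus <- mat[mat$strand_of_call == "+", ]
  expect_equal(plus$n_meth, 7L)
  expect_equal(plus$percent, 70.0)
  # the uncovered '-' row is present with zero total and undefined percent
  minus <- mat[mat$strand_of_call == "-", ]
  expect_equal(minus$coverage, 0L)
  expect_true(is.na(minus$percent))
})

test_that("counts conserve reads and strands stay consistent end to end", {
  t <- random_target(length_bp = 200, n_cpg = 5, seed = 101)
  cfg <- sim_config(per_cpg_methylation = 0.4, n_reads = 300,
                    substitution_rate = 0, homopolymer_indel_rate = 0,
                    conversion_efficiency = 1, quality_profile = "flat",
                    seed = 102)
  sim <- simulate_reads(t, cfg)
  idx <- build_converted_index(t)
  aln <- align_reads(sim$reads, idx)
  obs <- call_alignments(aln, idx)

  # strand consistency against simulation truth
  m <- merge(obs, sim$truth, by = "read_id")
  expect_true(all(m$strand_of_call[m$strand_origin %in% c("OT", "CTOT")] == "+"))
  expect_true(all(m$strand_of_call[m$strand_origin %in% c("OB", "CTOB")] == "-"))

  # count conservation: every overlapping read contributes exactly one
  # observation (meth, unmeth or nocall) per covered site
  mat <- accumulate(obs, t)
  n_reads_overlapping <- sum(aln$summary$status == "mapped")
  per_site <- tapply(mat$n_meth + mat$n_unmeth + mat$n_nocall,
                     mat$offset, sum)
  expect_true(all(per_site == n_reads_overlapping))  # full-span reads
})

test_that("per-CpG estimates track the simulated level at binomial accuracy", {
  t <- random_target(length_bp = 200, n_cpg = 5, seed = 111)
  p <- 0.3; n <- 400
  cfg <- sim_config(per_cpg_methylation = p, n_reads = n,
                    substitution_rate = 0, homopolymer_indel_rate = 0,
                    conversion_efficiency = 1, quality_profile = "flat",
                    seed = 112)
  sim <- simulate_reads(t, cfg)
  idx <- build_converted_index(t)
  obs <- call_alignments(align_reads(sim$reads, idx), idx)
  mat <- accumulate(obs, t)
  est <- tapply(mat$n_meth, mat$offset, sum) /
    tapply(mat$coverage, mat$offset, sum)
  bound <- 3 * sqrt(p * (1 - p) / n)
  expect_true(all(abs(est - p) < bound))
})

test_that("the CpH channel reflects bisulfite conversion efficiency", {
  t <- random_target(length_bp = 200, n_cpg = 4, seed = 121)
  idx <- build_converted_index(t)
  run_cph <- function(eff, n_reads = 120, seed = 122) {
    cfg <- sim_config(conversion_efficiency = eff, n_reads = n_reads,
                      substitution_rate = 0, homopolymer_indel_rate = 0,
                      quality_profile = "flat", seed = seed)
    sim <- simulate_reads(t, cfg)
    call_alignments(align_reads(sim$reads, idx), idx, channel = "cph")
  }
  full <- run_cph(1.0)
  expect_true(all(full$state == "unmethylated"))
  none <- run_cph(0.0)
  expect_true(all(none$state == "methylated"))
  partial <- run_cph(0.98, n_reads = 300, seed = 123)
  frac <- mean(partial$state == "methylated")
  n_obs <- nrow(partial)
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / n_obs))
})

test_that("bedGraph output uses 0-based half-open coordinates", {
  target <- mk_target("AACGTT", start = 101L)
  obs <- data.frame(read_id = "r1", target_name = "amp1", offset = 2L,
                    genome_pos = 103L, state = "methylated",
                    strand_of_call = "+", stringsAsFactors = FALSE)
  mat <- accumulate(obs, target)
  bg <- tempfile(fileext = ".bedGraph")
  write_bedgraph(mat, target, bg)
  df <- read.table(bg, sep = "\t", header = TRUE)
  expect_equal(df$start, rep(102L, 2))
  expect_equal(df$end, rep(103L, 2))
  expect_equal(df$chrom, rep("chrT", 2))
})
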
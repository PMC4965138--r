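test_that("the pattern space doubles with every CpG", {
  expect_equal(pattern_space_size(3), 8)
  expect_equal(pattern_space_size(0), 1)
  expect_equal(pattern_space_size(10), 1024)
  expect_error(pattern_space_size(-1), class = "ampliMeth_bad_config")
})

test_that("span selection honours the coverage percentage", {
  t <- random_target(length_bp = 200, n_cpg = 4, seed = 161)
  summary <- data.frame(
    read_id = c("full", "half", "most"),
    status = "mapped", target_name = "amp1", strand_label = "OT",
    score = 1, identity = 1,
    target_start = c(0L, 0L, 10L), target_end = c(200L, 100L, 190L),
    stringsAsFactors = FALSE)
  aln <- structure(list(summary = summary, alignments = list()),
                   class = "amplicon_alignments")
  expect_equal(select_spanning_reads(aln, t, 100), "full")
  expect_equal(select_spanning_reads(aln, t, 80), c("full", "most"))
  expect_setequal(select_spanning_reads(aln, t, 50), c("full", "half", "most"))
  expect_error(select_spanning_reads(aln, t, 0), class = "ampliMeth_bad_config")

  # brute-force recount on simulated mixed spans
  cfg <- sim_config(n_reads = 200, read_span = c(0.4, 1), substitution_rate = 0,
                    homopolymer_indel_rate = 0, conversion_efficiency = 1,
                    quality_profile = "flat", seed = 162)
  sim <- simulate_reads(t, cfg)
  aln2 <- align_reads(sim$reads, build_converted_index(t))
  ids <- select_spanning_reads(aln2, t, 75)
  s <- aln2$summary
  brute <- s$read_id[s$status == "mapped" &
                       (s$target_end - s$target_start) >= 0.75 * 200]
  expect_setequal(ids, brute)
})

mk_obs <- function(read_id, states, offsets = NULL, target = "amp1") {
  if (is.null(offsets)) offsets <- seq_along(states)
  data.frame(read_id = read_id, target_name = target, offset = offsets,
             genome_pos = 100L + offsets, state = states,
             strand_of_call = "+", stringsAsFactors = FALSE)
}

test_that("patterns aggregate, rank and normalize per read", {
  t <- mk_target("ACGACGAAT")  # CpGs at offsets 1 and 4
  obs <- do.call(rbind, lapply(1:10, function(i) {
    mk_obs(paste0("r", i), c("methylated", "unmethylated"), c(1L, 4L))
  }))
  pt <- extract_patterns(obs, t)
  expect_equal(pt$pattern, "MU")
  expect_equal(pt$frequency, 1.0)

  obs2 <- rbind(
    do.call(rbind, lapply(1:3, function(i) {
      mk_obs(paste0("m", i), c("methylated", "methylated"), c(1L, 4L))
    })),
    mk_obs("u1", c("unmethylated", "unmethylated"), c(1L, 4L)))
  pt2 <- extract_patterns(obs2, t)
  expect_equal(pt2$pattern, c("MM", "UU"))
  expect_equal(pt2$frequency, c(0.75, 0.25))
  expect_equal(sum(pt2$frequency), 1)

  # a read with any nocall is excluded entirely
  obs3 <- rbind(obs2, mk_obs("n1", c("methylated", "nocall"), c(1L, 4L)))
  expect_identical(extract_patterns(obs3, t)$count, pt2$count)
  # as is a read missing a site
  obs4 <- rbind(obs2, mk_obs("p1", "methylated", 1L))
  expect_identical(extract_patterns(obs4, t)$count, pt2$count)
})

test_that("equal counts rank lexicographically for deterministic output", {
  t <- mk_target("ACGACGAAT")
  obs <- rbind(mk_obs("a", c("unmethylated", "methylated"), c(1L, 4L)),
               mk_obs("b", c("methylated", "unmethylated"), c(1L, 4L)))
  expect_equal(extract_patterns(obs, t)$pattern, c("MU", "UM"))
})

test_that("independent half-methylated CpGs fill the pattern space uniformly", {
  t <- random_target(length_bp = 100, n_cpg = 3, seed = 171)
  cfg <- sim_config(per_cpg_methylation = 0.5, n_reads = 5000,
                    substitution_rate = 0, homopolymer_indel_rate = 0,
                    conversion_efficiency = 1, seed = 172)
  truth <- simulate_reads(t, cfg)$truth
  # feed truth states through the pattern extractor as observations
  obs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    st <- strsplit(truth$states[i], "")[[1]]
    mk_obs(truth$read_id[i],
           ifelse(st == "M", "methylated", "unmethylated"),
           enumerate_cpg_sites(t)$offset)
  }))
  pt <- extract_patterns(obs, t)
  expect_equal(nrow(pt), 8L)
  bound <- 3 * sqrt(0.125 * 0.875 / 5000)
  expect_true(all(abs(pt$frequency - 0.125) < bound))
  expect_lte(nrow(pt), pattern_space_size(3))
})

test_that("cross-sample comparison unions patterns and zero-fills absences", {
  t <- mk_target("ACGACGACGAAT")  # 3 CpGs
  offs <- enumerate_cpg_sites(t)$offset
  obsA <- do.call(rbind, lapply(1:4, function(i) {
    mk_obs(paste0("a", i), rep("methylated", 3), offs)
  }))
  obsB <- do.call(rbind, lapply(1:6, function(i) {
    mk_obs(paste0("b", i), rep("unmethylated", 3), offs)
  }))
  tabs <- list(A = extract_patterns(obsA, t), B = extract_patterns(obsB, t))
  cmp <- compare_patterns(tabs)
  expect_equal(cmp$pattern, c("UUU", "MMM"))  # ranked by total count
  expect_equal(cmp$A, c(0, 1))
  expect_equal(cmp$B, c(1, 0))

  # a single sample's comparison is its own ranked table
  solo <- compare_patterns(tabs["A"])
  expect_equal(solo$pattern, tabs$A$pattern)
  expect_equal(solo$A, tabs$A$frequency)

  txt <- tempfile(fileext = ".txt")
  write_pattern_report(cmp, txt)
  lines <- readLines(txt)
  expect_true(any(grepl("^# target amp1$", lines)))
  expect_true(any(grepl("^UUU\t6\t", lines)))
})

test_that("two samples from one mixture agree within multinomial bounds", {
  t <- random_target(length_bp = 120, n_cpg = 4, seed = 181)
  mix <- list(patterns = c("MMMM", "UUUU"), weights = c(0.7, 0.3))
  offs <- enumerate_cpg_sites(t)$offset
  tabs <- lapply(c(s1 = 191, s2 = 192), function(seed) {
    cfg <- sim_config(per_cpg_methylation = mix, n_reads = 2000,
                      substitution_rate = 0, homopolymer_indel_rate = 0,
                      conversion_efficiency = 1, seed = seed)
    truth <- simulate_reads(t, cfg)$truth
    obs <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      st <- strsplit(truth$states[i], "")[[1]]
      mk_obs(truth$read_id[i],
             ifelse(st == "M", "methylated", "unmethylated"), offs)
    }))
    extract_patterns(obs, t)
  })
  cmp <- compare_patterns(tabs)
  bound <- 2 * 3 * sqrt(0.7 * 0.3 / 2000)
  expect_true(all(abs(cmp$s1 - cmp$s2) < bound))
})
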
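test_that("bisulfite conversion follows the chemistry on the top strand", {
  # methylated CpG C is protected; the CpH C converts
  expect_equal(bisulfite_convert("ACGTCA", TRUE, 1.0, "OT"), "ACGTTA")
  # unmethylated: every C converts
  expect_equal(bisulfite_convert("ACGTCA", FALSE, 1.0, "OT"), "ATGTTA")
  # zero efficiency leaves the molecule untouched
  expect_equal(bisulfite_convert("ACGTCA", FALSE, 0.0, "OT"), "ACGTCA")
})

test_that("bottom-strand conversion acts on the G channel in forward coordinates", {
  # bottom-strand C pairs the forward G: protected when methylated
  expect_equal(bisulfite_convert("ACGTGA", TRUE, 1.0, "OB"), "ACGTAA")
  expect_equal(bisulfite_convert("ACGTGA", FALSE, 1.0, "OB"), "ACATAA")
  # CTOB product equals the OB product in forward coordinates
  expect_equal(bisulfite_convert("ACGTGA", TRUE, 1.0, "CTOB"),
               bisulfite_convert("ACGTGA", TRUE, 1.0, "OB"))
})

test_that("simulation is deterministic under a fixed seed", {
  t <- random_target(length_bp = 120, n_cpg = 4, seed = 5)
  cfg <- sim_config(n_reads = 50, seed = 77)
  a <- simulate_reads(t, cfg)
  b <- simulate_reads(t, cfg)
  expect_identical(a, b)
  cfg2 <- sim_config(n_reads = 50, seed = 78)
  expect_false(identical(simulate_reads(t, cfg2)$reads$sequence,
                         a$reads$sequence))
})

test_that("empirical per-CpG methylation converges to the configured level", {
  t <- random_target(length_bp = 150, n_cpg = 5, seed = 9)
  n <- 500
  # across replicates, per-site fractions must hit the 3-sigma binomial band
  # at close to its nominal coverage and be unbiased in aggregate
  frac <- sapply(1:20, function(s) {
    cfg <- sim_config(per_cpg_methylation = 0.3, n_reads = n,
                      substitution_rate = 0, homopolymer_indel_rate = 0,
                      conversion_efficiency = 1, seed = 1000 + s)
    truth <- simulate_reads(t, cfg)$truth
    states <- do.call(rbind, strsplit(truth$states, ""))
    colMeans(states == "M")
  })
  bound <- 3 * sqrt(0.3 * 0.7 / n)
  expect_gte(mean(abs(frac - 0.3) < bound), 0.97)   # nominal 0.997
  expect_lt(abs(mean(frac) - 0.3), 3 * sqrt(0.3 * 0.7 / (n * length(frac) / 5)))
})

test_that("pattern mixtures emit exactly the configured epialleles", {
  t <- random_target(length_bp = 100, n_cpg = 3, seed = 2)
  cfg <- sim_config(per_cpg_methylation = list(patterns = c("MMM", "UUU"),
                                               weights = c(0.5, 0.5)),
                    n_reads = 200, substitution_rate = 0,
                    homopolymer_indel_rate = 0, conversion_efficiency = 1,
                    seed = 4)
  truth <- simulate_reads(t, cfg)$truth
  expect_true(all(truth$states %in% c("MMM", "UUU")))
})

test_that("indel count grows with homopolymer content across reads", {
  t <- random_target(length_bp = 400, n_cpg = 6, seed = 31)
  cfg <- sim_config(n_reads = 1000, substitution_rate = 0,
                    homopolymer_indel_rate = 0.05,
                    conversion_efficiency = 1, seed = 8)
  sim <- simulate_reads(t, cfg)
  # homopolymer content varies across reads through conversion randomness
  hp <- vapply(sim$reads$sequence, function(s) {
    r <- rle(strsplit(s, "")[[1]])
    sum(r$lengths[r$lengths >= 2] - 1L)
  }, 0L, USE.NAMES = FALSE)
  expect_gt(suppressWarnings(cor(hp, sim$truth$n_indel, method = "spearman")), 0)
})

test_that("the decaying quality profile degrades only the 3' tail", {
  t <- random_target(length_bp = 200, n_cpg = 3, seed = 3)
  cfg <- sim_config(n_reads = 5, substitution_rate = 0,
                    homopolymer_indel_rate = 0, quality_profile = "decay",
                    seed = 10)
  q <- ampliMeth:::phred_to_int(simulate_reads(t, cfg)$reads$quality[1])
  expect_true(all(q[1:floor(0.8 * length(q))] == 35L))
  expect_lt(q[length(q)], 20L)
  cfg_flat <- sim_config(n_reads = 2, quality_profile = "flat", seed = 10)
  qf <- ampliMeth:::phred_to_int(simulate_reads(t, cfg_flat)$reads$quality[1])
  expect_true(all(qf == 35L))
})

test_that("zero requested reads yield empty FASTQ and truth", {
  t <- random_target(length_bp = 80, n_cpg = 2, seed = 1)
  sim <- simulate_reads(t, sim_config(n_reads = 0, seed = 1))
  expect_equal(nrow(sim$reads), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("run fixtures contain the promised files and reproduce byte-identically", {
  targets <- bind_targets(random_target("ampA", 120, 3, seed = 21),
                          random_target("ampB", 140, 4, chrom = "chrU",
                                        start = 2001, seed = 22))
  cfgs <- list(s1 = sim_config(n_reads = 20, seed = 301),
               s2 = sim_config(n_reads = 20, seed = 302))
  d1 <- file.path(tempdir(), "fix1"); d2 <- file.path(tempdir(), "fix2")
  unlink(c(d1, d2), recursive = TRUE)
  p1 <- write_run_fixture(targets, cfgs, d1)
  p2 <- write_run_fixture(targets, cfgs, d2)
  expect_length(p1$fastq, 2L)
  expect_true(all(file.exists(p1$target_file, p1$reference, p1$fastq, p1$truth)))
  for (f in c("targets.tsv", "reference.fasta", "s1.fastq", "s2.fastq",
              "truth.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
  truth <- read.table(p1$truth, sep = "\t", header = TRUE)
  expect_setequal(unique(truth$sample), c("s1", "s2"))
  expect_equal(nrow(unique(truth[, c("sample", "target_name")])), 4L)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(per_cpg_methylation = 1.2),
               class = "ampliMeth_bad_config")
  expect_error(sim_config(read_span = 0), class = "ampliMeth_bad_config")
  expect_error(sim_config(n_reads = -1), class = "ampliMeth_bad_config")
})
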
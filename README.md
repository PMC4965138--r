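# ampliMeth

Analysis of **targeted amplicon bisulfite sequencing** data in R: from raw
single-end FASTQ files to per-CpG methylation tables, read-level
methylation-pattern (epiallele) statistics and lollipop visualizations.

## Who this is for

Labs that amplify a panel of bisulfite-PCR (BSP) amplicons — typically a few
dozen regions of 150–650 bp with up to ~60 CpGs each — from bisulfite-treated
DNA, sequence the pooled amplicons on a bench-top instrument producing
single-end reads (semiconductor sequencers in particular, whose reads carry
characteristic homopolymer-length indel errors), and want per-sample,
per-CpG methylation calls plus cross-sample comparisons without running a
whole-genome bisulfite toolchain.

## What it computes

Bisulfite treatment converts unmethylated cytosine to uracil (read as T)
while 5-methylcytosine is protected, so after PCR the C/T state at a CpG
encodes methylation. The pipeline:

1. **Targets** — parses a tab-separated target file (`name`, `chrom`,
   `start`, `end`, `strand`; 1-based closed coordinates, so length =
   `end − start + 1`), attaches reference sequence from any FASTA (genomic
   contigs or per-amplicon records) and enumerates CpG sites.
2. **QC** — clips 3' bases with phred < 20 (configurable), applies an
   optional minimum-length filter, and reports before/after summary
   statistics (lengths, GC, per-position quality, duplicates).
3. **Alignment** — a self-contained *three-letter* aligner: reads and
   amplicon references are C→T / G→A converted so that methylation
   differences vanish, and each read is scored semi-globally (read global,
   target ends free, affine gaps: match +1, mismatch −3, gap open −5,
   extend −1) against every target in the strand states of the library —
   OT/OB for directional, plus CTOT/CTOB for non-directional (the default).
   Score ties are reported as ambiguous and excluded from calling.
4. **Methylation calling** — at each covered CpG, C/T (top strand) or G/A
   (bottom strand, forward coordinates) gives a methylated/unmethylated
   observation; everything else is a nocall. CpH positions form a separate
   side channel whose methylated fraction estimates conversion failure.
   A bedGraph-style per-site file (0-based half-open) is written per sample.
5. **Filtering** — three call-level filters: a minimum-coverage cutoff
   (`-r`, default 10), removal of sites whose coverage falls below the
   per-sample/target **mean − 1 SD** (uniform amplicon coverage is
   expected, so these are outliers), and a strand filter keeping only calls
   on the strand recorded in the target file.
6. **Patterns** — reads spanning ≥ `p`% of a target (default 100%)
   contribute one epiallele string over its CpGs (an amplicon with 3 CpGs
   has 2³ = 8 possible patterns); patterns are ranked by frequency and
   compared across samples.
7. **Report** — one final table (row per CpG, a `n_meth`/`n_unmeth`/`percent`
   triplet per sample), lollipop diagrams in two spacings (CpGs equally
   spaced, or spaced by true chromosomal coordinate) each with a
   machine-readable sidecar TSV, run statistics, and an optional
   concordance check against an external per-CpG beta-value table
   (per-sample Pearson r, median r, median r²).

A **synthetic-read simulator** with known truth (configurable per-CpG
methylation levels or pattern mixtures, bisulfite conversion efficiency,
all four bisulfite strand origins, substitution and homopolymer indel
errors, decaying 3' quality) makes every stage testable at desk scale.

## Worked example

```r
library(ampliMeth)

# two synthetic amplicons and two samples with different methylation levels
targets <- rbind(random_target("ampA", 220, 5, chrom = "chrT", start = 1001, seed = 201),
                 random_target("ampB", 240, 4, chrom = "chrU", start = 5001, seed = 202))
class(targets) <- c("target_set", "data.frame")
cfgs <- list(
  s1 = sim_config(per_cpg_methylation = 0.8, n_reads = 120, seed = 211,
                  substitution_rate = 0, homopolymer_indel_rate = 0,
                  conversion_efficiency = 1, quality_profile = "flat"),
  s2 = sim_config(per_cpg_methylation = 0.2, n_reads = 120, seed = 212,
                  substitution_rate = 0, homopolymer_indel_rate = 0,
                  conversion_efficiency = 1, quality_profile = "flat"))
fx <- write_run_fixture(targets, cfgs, "example_run_input")

cfg <- validate_config(fx$target_file, fx$reference, fx$fastq,
                       output_dir = "example_run", min_reads_per_cpg = 5)
res <- run_pipeline(cfg)
head(res$result_table[, c("target_name", "genome_pos", "s1.percent", "s2.percent")], 3)
```

```
  target_name genome_pos s1.percent s2.percent
1        ampA       1002   73.58491   18.03279
2        ampA       1056   73.58491   16.39344
3        ampA       1110   81.13208   18.03279
```

Each row is one CpG; `s1.percent` is 100·n_meth/(n_meth+n_unmeth) for that
sample at that site. Sample s1 was simulated at 80% methylation and s2 at
20%, and the pipeline recovers that separation from the reads alone. The
run directory contains `qc/`, `align/`, `calls/`, `filters/`, `patterns/`
and `report/` with all per-stage outputs, including
`report/final_table.tsv` and the lollipop figures plus sidecars.

A command-line wrapper over the same functions ships at
`inst/cli/amplimeth.R`:

```sh
Rscript inst/cli/amplimeth.R -t targets.tsv -g reference.fasta \
    -o run_dir -l NONDIR -q 20 -r 10 -p 100 sample1.fastq sample2.fastq
```

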
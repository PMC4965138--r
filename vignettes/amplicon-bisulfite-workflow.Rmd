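---
title: "Targeted amplicon bisulfite sequencing with ampliMeth: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted amplicon bisulfite sequencing with ampliMeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliMeth)
```

## The measurement model

Bisulfite treatment deaminates unmethylated cytosine to uracil, which PCR
amplifies and the sequencer reads as thymine; 5-methylcytosine is
protected. After amplification of the two parental strands, a
non-directional library sequences molecules from four strand populations:

* **OT** — the bisulfite product of the original top strand;
* **OB** — the product of the original bottom strand;
* **CTOT**, **CTOB** — the PCR complements of OT and OB.

In forward target coordinates an OT/CTOT molecule carries methylation
information as C (methylated) versus T (unmethylated) at the C of each CpG,
while an OB/CTOB molecule carries it as G versus A at the paired G — the
bottom-strand cytosine. Directional libraries restrict sequencing to OT and
OB. Because mammalian CpG methylation information is strand-resolved here,
observations are kept per call strand (`+` for OT/CTOT, `-` for OB/CTOB)
and only merged where the strand filter admits them.

## Coordinate conventions

The target file is 1-based and fully closed (span length
`end − start + 1`); this is the convention under which the shipped amplicon
coordinate fixture reproduces its printed lengths exactly. Internal offsets
are 0-based; every BED-family output (the per-site bedGraph intermediate)
uses 0-based half-open coordinates per that standard. The target `strand`
column never reverse-complements the stored sequence — it is metadata
consumed solely by the strand filter.

## Alignment in three-letter space

Instead of wrapping an external mapper, the package aligns in converted
space: every target is stored with its full C→T and G→A conversions, and a
read is tried as

| state | read form | target form |
|-------|-----------|-------------|
| OT    | C→T(read) | C→T(target) |
| CTOT  | C→T(revcomp(read)) | C→T(target) |
| CTOB  | G→A(read) | G→A(target) |
| OB    | G→A(revcomp(read)) | G→A(target) |

so that methylation-induced C/T (or G/A) differences vanish and an
error-free read aligns with zero mismatches whatever its methylation
pattern. Amplicon references are short (hundreds of bp), so full dynamic
programming per read × target × state is affordable: the Needleman–Wunsch /
semi-global machinery of Biostrings (`pairwiseAlignment`, read global,
target ends free, affine gaps) provides the DP core, and the package owns
the bisulfite logic around it — candidate enumeration, strand labelling,
thresholds and tie handling.

Default scoring is match +1, mismatch −3, gap open −5, gap extend −1. The
deliberately cheap extension tolerates the one-base homopolymer
length errors typical of semiconductor sequencing without letting gaps
proliferate. A candidate is accepted when its converted-space identity
(identical columns / alignment columns) reaches 0.80 and it spans at least
30 target bp (or the configured minimum read length). An exact score tie
between the top two *acceptable* candidates across targets and strand
states is reported `ambiguous` and excluded from calling — conservative
unique-mapping practice; tied candidates that would fail the thresholds
anyway are plain `unmapped`. Read `N` bases score as mismatches and never
produce a methylation call.

## Calling, filtering, patterns

**Calling.** At each CpG whose informative base lies inside the aligned
span, the original (unconverted) read base gives methylated/unmethylated;
gaps, `N` and non-concordant bases give `nocall`. CpH cytosines (forward C
not followed by G; forward G not preceded by C on the bottom strand) run
through the same rule into a separate side channel: since CpH methylation
is rare in mammals, its methylated fraction estimates bisulfite conversion
failure. Reads are *not* discarded for high CpH methylation — the channel
is diagnostic only.

**Filtering.** Three call-level filters, in narrative order:

1. *Minimum coverage*: remove sites with fewer than `r` informative reads
   (default 10 — surfaced prominently because it is this package's own
   default, not an inherited one).
2. *Mean − 1 SD*: amplicon coverage should be uniform within one
   sample/target, so any site whose total coverage falls strictly below the
   group mean minus one sample (n−1) standard deviation is an extreme
   outlier. The statistics are computed per (sample, target, call strand)
   over all sites with nonzero coverage — not just survivors of filter 1 —
   which makes the stage idempotent; groups with fewer than two covered
   sites are never filtered, and uniform groups (SD 0) keep everything
   because the inequality is strict.
3. *Strand*: keep only calls on the strand recorded in the target file.

Filters only flag rows; counts are never altered, and removed calls are
written to a diagnostics log with their reasons.

**Patterns.** Reads whose aligned span covers at least `p`% of the target
(default 100%) contribute one epiallele: the ordered M/U states of all the
target's CpGs observed on that single molecule. A read that passes the span
test but misses any CpG, or has any `nocall` among them, is excluded
entirely — partial patterns would fragment the 2^n space. Patterns are
ranked by count with lexicographic tie-breaks for deterministic output, and
compared across samples as a frequency table over the union of observed
patterns (absent cells are 0).

## The synthetic-data generator

The simulator emulates a realistic amplicon run so each stage can be tested
against known truth: per-read strand origin (uniform over the library's
strand states), per-CpG methylation states (independent Bernoulli per site,
or an explicit pattern mixture for epiallele tests), bisulfite conversion
with configurable efficiency applied to every unprotected cytosine of the
appropriate strand, uniform read placement at a configurable span fraction,
substitution errors per base and a homopolymer error model: each maximal
run of length L ≥ 2 gains or loses one base with probability
min(0.5, rate·(L−1)) — a single parameter reproducing the over-/under-call
signature of flow-based sequencing. Defaults are fixed once as study
conditions: 380 reads per amplicon, conversion efficiency 0.99,
substitution rate 0.01, homopolymer rate 0.01, non-directional library,
full-span reads, and a Q35 quality plateau decaying linearly to Q12 over
the final 15% of the read so the 3' clipper has realistic work.

What the simulator does **not** model: flow-space signal, adapters and
barcodes (inputs are post-demultiplex), PCR amplification bias, chimeric
reads, strand-asymmetric methylation, or sequence-dependent conversion
resistance. Passing tests therefore demonstrate correctness of the
algorithms under the stated error model, not performance on any particular
instrument run.

## Numerical and design choices

* **3' trimming** is the simplest rule satisfying "clip low-quality bases
  at the read end": remove the contiguous trailing run below the
  threshold. No sliding windows or sum-minimization.
* **Duplicates** are reported, never removed.
* **Seeds**: all simulation randomness flows from explicit integer seeds;
  per-sample/target seeds in fixture generation are derived
  deterministically (and kept inside 32-bit range), so identical
  configuration reproduces byte-identical FASTQ and final tables.
* **Degenerate inputs**: empty target files parse to empty sets; targets
  without CpGs yield empty site lists; reads trimmed to zero length are
  dropped before alignment; zero-coverage sites stay in the matrix with
  undefined percent; samples with fewer than two array-overlap positions
  get `NA` concordance and are excluded from the medians.
* **Figures**: every lollipop plot writes a sidecar TSV of exactly the
  plotted values, so graphical output is testable without image diffing;
  filtered cells are drawn as gaps, not zeros.
* **Paired-end input** is accepted but processed as independent single-end
  files with a warning — the target instrument class is single-end and no
  mate-merging algorithm is defined here.
* **Problem sizes in tests**: simulation-backed checks use 120–5,000 reads
  on 100–600 bp amplicons — large enough for the stated 3σ binomial and
  multinomial bounds to be meaningful, small enough to run routinely.

## Known limitations

* The aligner is O(read × target) per candidate and meant for amplicon
  panels, not genomes; there is no indexing/seeding layer.
* MSP (methylation-specific PCR) designs are not scored.
* No SNP-aware calling: a C/T SNP at a CpG is indistinguishable from a
  methylation difference.
* Beta-value concordance is a generic operation; its numeric outcome
  depends entirely on the user's data.
* CHH/CHG subdivision of the CpH channel is out of scope.
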
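---
title: "Estimating bisulfite conversion efficiency from telomeric repeats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating bisulfite conversion efficiency from telomeric repeats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloconv)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) infers cytosine methylation from
whether a cytosine survives bisulfite treatment: unmethylated cytosines are
deaminated and read as thymine, methylated ones stay cytosine.  The assay
silently assumes conversion runs to completion.  When it does not, every
unconverted unmethylated cytosine is a false methylation call.  A per-sample
estimate of the conversion efficiency is therefore a basic QC quantity, but
the common ways of getting one — aligning reads to a converted genome and
reading off non-CpG methylation, or adding an exogenous spike-in of known
methylation state — are respectively slow and assumption-laden.

Vertebrate telomeres offer a shortcut.  They are kilobases of the exact
repeat `TTAGGG` (G strand) / `CCCTAA` (C strand).  The C-strand repeat
carries three cytosines per six-base block, all in non-CpG context (two CpC,
one CpT), and telomeric DNA is essentially unmethylated.  Telomeric reads
are also trivial to recognise *without alignment*: any read containing a
long exact run of repeat blocks is telomeric.  So the telomere is a native
spike-in: scan the FASTQ, collect C-strand repeat blocks, and the fraction
of block cytosines still read as `C` estimates the unconverted ratio (UCR)
directly.

One caveat is inherited by any such method: a surviving cytosine can be a
conversion failure or a genuinely methylated base.  The two are
indistinguishable at a single site, so the UCR is the *sum* of the
conversion-failure rate and the residual methylation rate, and the reported
conversion efficiency `1 - UCR` is a lower bound on the chemical efficiency.
The package never pretends to separate the two components; what it can do
(below) is use the *distribution* of unconverted cytosines across blocks to
distinguish random failure from clustered artefacts.

## Read dialects and block classification

In a directional paired-end library, read 1 reports the bisulfite-converted
original strand and read 2 its complement.  Four block patterns follow from
the biochemistry:

| file   | C-strand block        | G-strand block |
|--------|-----------------------|----------------|
| fastq1 | `[CT][CT][CT]TAA`     | `TTAGGG`       |
| fastq2 | `TTA[AG][AG][AG]`     | `CCCTAA`       |

A C-strand block in read 1 shows an unconverted site directly as `C` at
block positions 1–3 (site1–site3, indexed 5'→3' on the C strand).  In read 2
the same information appears reverse-complemented: a `G` at positions 4, 5,
6 marks site3, site2, site1.  Blocks are classified N0–N3 by how many of
their three sites are unconverted; `classify_block()` exposes the mapping
and the scanner applies it to every block of every matched run.

Two consequences of the patterns are worth spelling out.  First, the
G-strand patterns contain no cytosine, so G-strand reads carry no conversion
information; they are counted (they dominate telomeric read counts in real
data because of PCR GC bias) but contribute no blocks.  Second, a *fully
unconverted* C-strand run — `CCCTAA` repeats in read 1 — matches the
C-strand pattern with every block N3.  It is deliberately classified as a
C-strand N3 run and never as G strand: that choice is what makes untreated
DNA contamination visible at all.

## Finding repeat runs

A read's telomeric run is the longest chain of consecutive, complete,
non-overlapping six-base blocks at any phase offset; partial blocks at the
run edges are ignored so that block tallies are well defined.  The scanner
computes, per pattern, `run[i] = match(i) ? 1 + run[i+6] : 0` backwards over
the read (implemented in C++; exact and linear in read length).  A greedy
regular-expression search is *not* equivalent: a short leftmost match can
overlap and truncate a longer run in a different phase, which is why the
test suite pins the scanner against a brute-force sliding-window enumerator
over every start position.

Per read, the longer of the C-strand and G-strand runs decides the strand
origin, with ties going to the C strand (conversion information is never
discarded).  A read is called telomeric when its run has at least
`min_blocks` blocks.  The default of 8 sits where the run-length
distribution of real WGBS data plateaus: shorter exact runs occur by chance
in genomic sequence, while a 48-base exact run essentially never does (in
hg38, nearly all `(TTAGGG)7+` matches are telomeric or subtelomeric).  The
`block_count_distribution()` diagnostic always scans with threshold 1 so the
plateau can be inspected per sample; `plot()` on a fit draws it.

## The binomial block model

Treat each site's conversion failure as an independent Bernoulli event with
probability *p* (the UCR).  The number of unconverted sites in a block is
then Binomial(3, *p*), so the expected fractions of N1/N2/N3 blocks are

  R1 = 3p(1−p)²,  R2 = 3p²(1−p),  R3 = p³.

With *p* of a few tenths of a percent, N1 blocks outnumber N2 by ~500:1 and
N3 is expected to be absent; essentially all the information sits in R1.
`fit_binomial()` therefore estimates *p* by inverting R1 alone, and then
*recomputes* R2 and R3 at the estimate as a model check: if unconverted
cytosines really are rare random events, observed and expected R2 agree
(this is the `residuals()` of the fit; the R1 residual is zero by
construction).  Excess N2/N3 signals non-random causes — enzymatic non-CpG
methylation or contamination.

Numerical notes for the inversion.  R1(p) is strictly increasing on
[0, 1/3] with maximum 4/9, so the root is bracketed and unique;
`ucr_from_r1()` bisects to an absolute tolerance of 1e−12.  An observed R1
above 4/9 has no solution — the equal-rate model is then simply wrong for
the data (e.g. one site far more methylated than the others) and the
function says so rather than returning a boundary value.  Exactly at the
boundary the inverse is returned as 1/3 directly: the derivative vanishes
there, so a residual-sign bisection cannot localise the root better than a
few 1e−9 and the closed-form answer is preferable.  `site_ucr()` refuses a
zero-block denominator with an explicit error — "no telomeric blocks" is
not the same observation as "UCR = 0".

Per-site UCRs (`site_ucr()`) are plain binomial proportions per site and are
reported next to the R1-derived estimate; the package does not reconcile
them beyond reporting both, since systematic disagreement is itself
diagnostic.  Binomial standard errors accompany every UCR in the fitted
object and `summary()` (delta-method for the R1-derived one); they are
deliberately kept out of the TSV report, whose columns are fixed counts and
point estimates.

## Contamination detection

Under the random model the expected N3 count is ~p³ per block — zero for
any realistic sample size.  Observed N3 blocks have two known causes with
opposite spatial signatures: untreated genomic DNA contributes whole reads
of unconverted repeats (N3 blocks *cluster* in a few reads), while rare
enzymatic methylation scatters them (at most one N3 per read, in practice).
`assess_contamination()` encodes this as a two-parameter heuristic: reads
holding at least `cluster_min` N3 blocks (default 2) are "N3-rich", and if
rich reads jointly hold at least `concentration_min` (default 0.5) of all N3
blocks the verdict is `suspected_contamination`; otherwise `dispersed`; with
no N3 at all, `none`.  The thresholds are honest heuristics, not estimates
of anything — the underlying distinction is qualitative — and both are
arguments of `teloconv()` and CLI flags.

## The forward file is primary

Both mates are analysed, independently and with the same machinery, but the
forward-file estimates are the primary ones.  Reverse reads of telomeric
fragments are sequenced from the telomere inward, so they can run off the
telomere end and pick up spurious terminal repeat blocks; empirically their
UCRs come out slightly higher.  The paired report keeps the fastq2 row as a
concordance diagnostic.  The simulator does not inject this asymmetry (its
read 2 is the exact reverse complement of read 1), which is precisely what
the read1/read2 symmetry test exploits.

## What the simulator does and does not emulate

`simulate_wgbs()` generates the study conditions end to end: C-strand reads
as concatenated blocks with independent per-site Bernoulli unconversion,
G-strand reads, optional fully-unconverted contaminant reads, uniform random
background, random repeat phase offsets of 0–5 bases, and a per-read truth
ledger restricted to the complete blocks a scanner can recover.  Defaults
are fixed once at realistic values: `p_site = 0.004` per site (telomeric
UCRs in public WGBS sit below 0.5% with no inter-site difference),
`read_length = 150`, `telomeric_fraction = 5e-4` (the order of the telomeric
share of a human genome: ~46 ends × ~10 kb / 3.1 Gb), `g_strand_fraction =
0.5`, no contamination, no sequencing error.

Deliberately not modelled: quality-score structure (qualities are constant
and never used), adapters, subtelomeric junctions, the G/C-strand PCR
imbalance seen in real data, the forward/reverse UCR asymmetry, and —
by default — sequencing error (a uniform substitution rate is available for
robustness studies; with it the truth ledger becomes approximate).
Consequently, passing tests demonstrate correctness of the *method* under
its own model: exact run recovery, tally bookkeeping, estimator calibration,
and contamination discrimination.  They do not certify behaviour on
degraded real-world reads, where sequencing errors truncate runs (slightly
shrinking the usable block count) and can flip individual sites in either
direction.

## Problem sizes and test design

The calibration checks run 20 simulated replicates of 50,000 telomeric
150-bp reads at p = 0.005 (~1.2 million blocks each); every replicate's
per-site UCRs and R1-derived estimate must fall within 4 binomial standard
errors of truth and the replicate means within 2 standard errors of the
mean, with observed R2 matching predicted R2 at the same tolerances.
Contamination checks spike 0.1% unconverted reads (verdict must flip to
suspected) and, separately, elevate site1 to 50% (N3 present but dispersed;
the binomial fit is then reported inconsistent, by design, while the
contamination verdict still evaluates).  The scanner is pinned to the
brute-force enumerator on 1,000 telomere-enriched random sequences, and the
R1 inversion to 1e−9 over a 100-point grid of the full identifiable range.
`scripts/acceptance.R` re-runs a scaled version of the same computations
(10 replicates of 25,000 telomeric reads) from scratch at an arbitrary seed
and writes the headline numbers as JSON.

## Known limitations

- Telomeres may not share the conversion kinetics of bulk chromatin;
  the estimate is a telomere-local efficiency used as a genome-wide proxy.
- UCR conflates conversion failure with genuine non-CpG methylation; in
  cell types with substantial non-CpG methylation (ES cells, neurons) the
  efficiency bound is conservative.
- Exact-match scanning ignores sequencing errors inside runs; a read with
  an error mid-run contributes its longest clean segment only (and is
  dropped entirely below `min_blocks`).  This biases block counts down but
  leaves per-site rates nearly untouched.
- The repeat patterns are vertebrate `TTAGGG`; other telomere repeats need
  different patterns (the four block matchers are a single, small, compiled
  table — adaptable, but not a runtime option).
- Samples with very short telomeres, heavy degradation, or capture-based
  protocols may simply not contain enough telomeric reads; the report then
  carries `insufficient_telomeric_reads` (fewer than 100 blocks) rather
  than a noise-dominated estimate.
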
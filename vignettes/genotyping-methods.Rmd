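---
title: "Genotyping CRISPR-edited clones from amplicon reads: methods and assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotyping CRISPR-edited clones from amplicon reads: methods and assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(editcall)
```

## The problem

A CRISPR-Cas9 ribonucleoprotein cuts genomic DNA at a programmed site;
non-homologous end joining (NHEJ) repairs the break, usually leaving a small
insertion or deletion. A single edited cell is expanded into a clone, the
target window is PCR-amplified, and the amplicon is sequenced to a depth of
tens of thousands of reads. The genotyping question is: **which allele
sequences does this clone carry, and in what proportions?**

The difficulty is that the read pool mixes three things:

1. reads from the clone's true alleles (each allele may carry zero, one, or
   several indels on one amplicon copy);
2. reads with amplification/sequencing errors layered on top of a true
   allele (substitutions dominate; spurious 1-bp indels are rarer);
3. occasional artifact reads (chimeras, contamination).

At a per-base substitution error rate of a few parts per thousand, most
reads over a ~300-bp amplicon carry at least one error, so the set of
*distinct* read sequences is enormous even for a clone with two alleles.

## The pipeline

`genotype_sample()` (and `run_pipeline()` for a directory of samples)
implements the following steps.

**1. Pair joining (optional).** Overlapping mate pairs are merged by
scanning every overlap length of at least `min_overlap` (default 6) and
taking the one with the lowest mismatch fraction, provided it does not
exceed `max_mismatch_frac` (default 0.08); mismatched overlap columns take
the higher-quality base. Pairs with no acceptable overlap are counted and
excluded.

**2. Unique-read collapsing and the read-count cutoff.** Reads are
collapsed to unique sequences with counts. A unique sequence is retained
only if its count is at least the cutoff (default **30**, inclusive). The
statistical logic: a *true allele* sequence is re-observed thousands of
times, while any *specific* error-bearing sequence requires the same error
at the same position in many independent reads. With a per-base error rate
$e$ and amplicon length $L$, the expected count of one specific single-error
sequence is roughly $n\,p_a\,(e/3)(1-e)^{L-1}$ for an allele at fraction
$p_a$ of $n$ reads — tens of reads at $n = 50{,}000$, and far below the
count of the parent allele. The cutoff therefore separates alleles from
error sequences without any error model fitting.

**3. Alignment.** Each retained unique sequence is aligned to the reference
region with an affine-gap Smith–Waterman aligner (match $+2$, mismatch
$-3$, a gap of length $k$ costs $5 + 2k$), on both strands, implemented in
C++. Tie-breaking is deterministic: among equal-scoring alignments the
traceback minimizes the number of gap openings and then prefers gap
extension and diagonal moves, so residual indel-placement ambiguity is
resolved consistently (and canonicalized in the next step). Alignments
covering less than `min_aligned_frac` of the read (default 0.5) or below
`min_identity` over aligned columns (default 0.7) are set aside as
artifacts.

**4. Indel extraction and left-normalization.** Every insertion and
deletion in the alignment is converted to a VCF-style record
(CHROM, POS, REF, ALT) and shifted to its leftmost equivalent placement
through repeat context, with the anchor base on the left (or flagged
right-anchored at the region boundary). Substitution columns are
deliberately ignored: at these error rates a mismatch in a deeply supported
read is overwhelmingly an amplification error, and indels are the NHEJ
signal.

**5. Genotype signatures and major calls.** The *complete set* of
normalized indels on one read is that read's genotype signature (the empty
set is wild type). Unique reads with identical signatures are aggregated —
this is what makes the call robust to substitution errors on
high-count reads. A signature is a **major genotype** when its supporting
reads are at least `major_threshold` (default **1%**, inclusive) of the
sample's total processed reads. The *read contribution* — the fraction of
retained reads belonging to major genotypes — summarizes how completely the
major calls explain the retained data; values near 1 indicate a clean
single-clone sample.

## What the reported proportions mean

A subtlety worth stating explicitly: with the cutoff at 30, essentially
only *error-free* reads survive collapsing (each error-bearing sequence is
nearly unique). At $e = 0.003$ over a 296-bp amplicon, the error-free
fraction per read is $(1-e)^{296} \approx 0.41$, so the reported
`proportion` of a genotype estimates its share of **error-free reads over
total reads**, not its underlying allele fraction. Proportions of major
genotypes in a clean clone therefore sum to well below 1. Relative allele
fractions can be recovered by renormalizing the major proportions; this is
almost unbiased because the error-free probability is nearly identical
across alleles of similar length (a 15-bp deletion changes it by under 5%
relative). The validation suite checks called proportions against the
simulator's realized error-free counts for exactly this reason.

## A worked example

```{r example}
region <- ref_region("chrSim", 10001L, 10296L,
                     paste(sample(c("A", "C", "G", "T"), 296, replace = TRUE),
                           collapse = ""))
alleles <- list(random_signature(region),
                random_signature(region, cut_offset = 190L))
spec <- sim_spec(region, alleles, c(0.6, 0.4), n_reads = 8000)
sim <- simulate_clone_fastq(spec, file.path(tempdir(), "vignette_clone"))
report <- genotype_sample(sim$fastq, region, cutoff = 30)
report
```

The truth table written next to the FASTQ records, per allele, the reads
drawn (`n_assigned`) and the error-free reads (`n_exact`); the supporting
counts above match `n_exact`:

```{r truth}
sim$truth
```

The cutoff sweep reproduces the characteristic shape of cutoff-based
genotyping: the genotype count collapses by orders of magnitude as the
cutoff grows, while the major-genotype set does not change at all.

```{r sweep}
reads <- read_fastq(sim$fastq)
uniques <- collapse_unique(reads)
cutoff_sweep(uniques, nrow(reads), region, cutoffs = c(0L, 5L, 30L))
```

## The simulator, and what validation does and does not show

`sim_spec()`/`simulate_clone_fastq()`/`simulate_cohort()` generate clones
with known allele signatures, multinomial read assignment, independent
per-base substitution errors, rare spurious 1-bp indels, and optional
overlapping mate pairs — with a machine-readable truth table. The test
suite validates, among other properties: alignment scores against a
brute-force dynamic program; left-normalization against brute-force
enumeration of equivalent indel placements; and exact recovery of 2–4
allele clones at 50,000 reads with proportions within three binomial
standard errors of the realized truth.

These are *internal-consistency* guarantees. The simulator's error model
is deliberately simple (independent errors, uniform across positions and
cycles, no PCR jackpot amplification of early-cycle errors, no
context-dependent indel hotspots), so passing validation demonstrates that
the algorithms are implemented correctly — not that the default cutoff is
optimal for any particular instrument or chemistry. On real data the
cutoff sweep (`cutoff_sweep()`) is the practical tool for checking that
calls are stable over a range of cutoffs.

One generator design point: simulated signatures are always *canonical*,
i.e. realigning an allele's own haplotype reproduces its signature. Two
nearby deletions whose merged form costs one gap opening instead of two are
observationally indistinguishable from that merged form in read data, so
such candidates are redrawn rather than treated as a distinct truth.

## Parameter defaults at a glance

| Parameter | Default | Rationale |
|---|---|---|
| read-count cutoff | 30 | above the expected recurrence of any specific error sequence at typical depth; inclusive |
| major threshold | 1% of total reads | separates clone alleles (tens of percent) from residual artifacts; inclusive |
| match / mismatch | +2 / −3 | mismatches penalized more than matches reward, so errors do not rescue poor placements |
| gap open / extend | 5 / 2 | one long gap is cheaper than many short ones, matching single-cut NHEJ deletions |
| min aligned fraction | 0.5 | rejects chimeric half-alignments |
| min identity | 0.7 | rejects off-target or contaminant reads |
| pair-join overlap / mismatch | 6 / 0.08 | smallest overlap with acceptable false-join risk; tolerates end-of-read errors |

## Limitations

* Substitution-only alleles (e.g. HDR point edits) are invisible by
  design; the genotype unit is the indel set.
* Alleles below the major threshold, or clones sequenced so shallowly that
  an allele's error-free reads fall below the cutoff, are not called.
* Indel placement within perfect repeats is canonical (leftmost), not
  mechanistic: the reported POS is a convention, not an inference about the
  repair event.
* Large structural outcomes whose alignment no longer covers half the read
  (very large deletions relative to the amplicon, insertions of mobile
  elements) are filtered as artifacts rather than called.
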
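---
title: "Detecting and quantifying A-to-I RNA editing: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying A-to-I RNA editing: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(editscreen)
```

This vignette is the package's account of its statistical methods: the
models behind each stage, the defaults and why they were chosen, what the
synthetic-data generators do and do not emulate, and the numerical
corner-case decisions a user auditing results will want to know.

## The differential-editing screen

The screen takes a sites × samples matrix of per-site editing levels
(proportions of reads carrying G at a genomic A, in [0, 1], missing
allowed) with per-sample condition (tumor/normal) and optional pairing.
Its model is deliberately minimal: no distributional assumption on the
editing levels, a rank test per site, and FDR control across sites.

**Informative-site filter.** A site enters the screen only if it is
observed in both members of at least `min_pairs = 5` matched tumor/normal
pairs. The pairing metadata is used *only* here: editing pipelines emit
very sparse matrices, and the pair-count requirement guarantees each
tested site has same-patient support in both conditions.

**Test.** Each retained site is tested with an *unpaired* two-sided
Wilcoxon rank-sum test of all tumor against all normal values. A paired
signed-rank variant was considered and rejected as the default: cohorts
of this kind are heavily unbalanced (hundreds of tumors against ~100
normals), so restricting the test to complete pairs would discard most of
the tumor information; the unpaired test uses every observed value.

**Multiplicity and effect floor.** P-values from testable sites are
adjusted with the Benjamini–Hochberg step-up (the de facto FDR procedure
of this ecosystem) and a site is significant when `q < 0.05` *and* the
mean editing difference Δ = mean(tumor) − mean(normal) satisfies
|Δ| ≥ 0.05 — i.e. at least five percentage points of editing. The floor
matters: with hundreds of samples the rank test detects sub-percent
shifts that are biologically uninteresting and technically fragile.
Because whether the original 5% rule was signed or absolute is ambiguous,
both `direction = "both"` (default) and `"up_only"` (tumor-gained
editing only) are provided.

Numerical decisions:

* Exact enumeration of the rank-sum null is used when both groups have
  ≤ 8 values and there are no ties; otherwise the normal approximation
  with midrank tie correction and continuity correction. The switch point
  is where enumeration stops being meaningfully different from the
  corrected approximation at this data scale.
* A site where every value is identical carries no rank information and
  gets p = 1 (flagged `zero_variance`); a site with an empty group after
  missing-value removal is *untestable*: its p and q are missing, it is
  excluded from the BH denominator m, and it is reported rather than
  dropped.
* BH is computed over testable sites only; missing p-values stay missing.

## Feature annotation

Gene models come from GTF (feature rows as given; introns derived as exon
gaps) or BED12 (exons from blocks, CDS from the thick region, UTRs from
the exonic remainder with strand deciding which side is 5'; a zero-width
thick region marks the transcript noncoding). Two derived classes are
added per transcript: `upstream` and `downstream`, the `flank_len`
(default 1000 bp) windows outside the transcription boundaries, assigned
strand-aware in genome coordinates and clamped at position 1; and, for
transcripts with no CDS, an `ncRNA` interval spanning the body.

Annotation is **multi-label**: a single-base site receives every feature
class it overlaps across all transcripts, so a 3'UTR site is both `3UTR`
and `exon`. This mirrors how genome-annotation tooling tallies feature
bars, and it is the reason headline per-class counts can sum to more than
the number of sites. For single-label summaries a precedence mode is
provided (3UTR > 5UTR > CDS > intron > ncRNA > upstream > downstream).
`intergenic` is exclusive by construction.

Per-gene co-occurrence sets (`cooccurrence_sets()`) collect, for each
gene, the exact set of feature classes containing an edited site — the
table an UpSet plot draws. The structural `exon` label is dropped from
the sets by default, since it is implied by any UTR/CDS label and would
otherwise fold "3'UTR only" genes into a "3'UTR + exon" combination;
pass `drop = character()` to keep it.

## Amplicon quantification

Editing is validated by sequencing PCR amplicons templated from genomic
DNA (which cannot carry editing and serves as the genotype reference) and
from cDNA (which carries it), and comparing pileups at every A of the
amplicon.

* **G% denominator.** G% = 100·G/(A+C+G+T). Total depth, not A+G, is the
  default: stray C/T sequencing errors should dilute the editing signal
  rather than silently vanish from the denominator. `denominator = "ag"`
  provides the alternative.
* **Thresholds.** gDNA depth ≥ 100 with gDNA G% ≤ 1 confirms the site is
  genomically A (a heterozygote shows ~50%); cDNA G% ≥ 5 calls a site
  edited, mirroring the cohort screen's 5% effect floor; base and
  mapping quality ≥ 20 are conventional amplicon QC. None of these is
  canonical — all are configurable and recorded in the output.
* **SNP exclusion** is allele-aware: only a ref=A/alt=G record can
  explain away an A→G signal; records without allele information always
  match. A known-editing-site catalogue can be supplied through the same
  lookup for corroboration (annotation only, never exclusion).
* **Accounting.** Reads whose alignment deletes the site, and base calls
  failing the quality filter, are excluded from counts but tallied
  (`n_del_skipped`, `n_low_qual_skipped`), so depth plus tallies equals
  the quality-mapped reads overlapping the position — a conservation
  property the tests assert.
* **Strand.** Counts are taken as aligned; amplicons are strand-defined
  by their primers, so no reverse-complement inference is attempted.
  Minus-strand editing observed as T→C is out of scope here.
* Fold changes between conditions with a zero denominator are reported
  as infinite and flagged; the difference in percentage points is always
  defined and is the more stable statistic at low editing.

## Survival and assay statistics

Records with RFS of exactly 0 months (no follow-up) or beyond 120 months
(10-year truncation; 120.0 itself is retained) are excluded before any
survival statistic.

The "auto select best cutoff" stratification is re-implemented as an
exhaustive scan: every observed expression value within the 10th–90th
percentile is tried as a threshold, with *high* defined as strictly
greater; the two-group log-rank p is computed for each and the minimizer
returned, ties broken toward the more balanced split and then the
smaller cutoff. Because the minimum over many correlated tests is taken,
the selected p-value is anti-conservative; the scan returns the full
candidate table and its print method says so. No min-p correction is
applied — the statistic is reported as the original tool reports it, as
a stratification device rather than a calibrated test.

The hazard ratio is the Mantel–Haenszel form (O₂/E₂)/(O₁/E₁) from the
log-rank observed/expected table, with a 95% CI from the log-scale
variance 1/E₁ + 1/E₂ — chosen over a Cox fit because it lives entirely
inside the log-rank framework the stratification uses, and degrades
transparently (flagged undefined when a group has no events). Tied event
times enter the risk table simultaneously.

Reporter and densitometry normalizations are two-step ratios
(Firefly/Renilla then reference-condition mean; band/loading-control
then reference mean), making them invariant to rescaling of the
normalizer — a property the tests check. Group comparisons use one-way
ANOVA with Tukey HSD.

## What the synthetic generators emulate — and what they do not

* **Cohort matrices.** Null editing levels are i.i.d. Beta(2, 40) (mean
  ≈ 4.8%), matching the low background level typical of 3'UTR editing;
  differential sites shift the tumor mean additively by `delta` (default
  +0.15) with clipping at 1; cells go missing independently at 10%. The
  default desk scale is 100 pairs × 1,000 sites, a scaled-down stand-in
  for cohorts of ~800 tumors/~100 normals. Not emulated: per-sample
  coverage-driven missingness (which is *informative* in real data),
  site-to-site correlation within an Alu or a 3'UTR, batch effects, and
  subtype structure. Tests passing on these cohorts show the screen's
  statistical machinery is correct, not that real-cohort calls are free
  of coverage or mapping artifacts.
* **Amplicon reads.** Ungapped, full-length, Q40 reads with uniform
  substitution error (default 10⁻³) and per-read Bernoulli editing at
  the injected rate. No indels, PCR duplicates, primer artifacts, or
  quality-score structure: the pileup's CIGAR and quality handling is
  therefore exercised by hand-written alignments in the tests rather
  than by the simulator.
* **Survival cohorts.** Expression bimodal N(4, 0.5²)/N(8, 0.5²) on the
  log2 TPM scale so a true cutoff exists at 6; exponential event times
  with baseline hazard 1/60 per month and the high group's hazard
  multiplied by `hr_true`; censoring by per-patient Bernoulli draw with
  a uniform-on-(0, t) censor time. Real relapse hazards are not constant
  in time; the exponential choice makes the true HR exact and
  recoverable.

All generators are deterministic functions of their spec and seed.

## Verified properties and problem sizes

The test suite (and the acceptance script, for the first item) verifies,
at these desk scales chosen to keep a full run within a few minutes on
one CPU:

* realized false-discovery proportion of the full screen ≤ 0.05 and
  recovery of ≥ 90% of shifted sites, over 50 cohorts of 100 pairs ×
  1,000 sites;
* exact rank-sum p equal to full enumeration for group sizes ≤ 6 (200
  random inputs) and the approximation within 0.01 of a 10⁵-resample
  permutation p at 20 vs 20;
* BH equal to its step-up definition on 1,000 random p-vectors;
* amplicon G% within 3 binomial SDs of injected rates at depth 2,000
  over 20 seeds, with zero edited calls on error-free gDNA comparisons;
* annotation equal to a brute-force interval scan on 10,000 random
  probes against the toy gene model, including flank boundaries on both
  strands;
* Mantel–Haenszel HR within 20% of a true HR of 2 (n = 500, 50
  replicates), and the cutoff scan recovering the true bimodal split in
  ≥ 90% of HR = 3 cohorts.

## Known limitations

* The screen tests sites marginally; no shrinkage or information sharing
  across sites (a limma/DESeq2-style hierarchical model could add power
  at small n but changes the inferential contract).
* Subtype-stratified screening and covariate adjustment are out of
  scope; the screen answers the common tumor-vs-normal question only.
* The best-cutoff p-value is descriptive, not calibrated (see above).
* Gene-model parsing expects well-formed GTF/BED12; overlapping
  transcripts are handled (multi-label), but trans-spliced or
  circular models are not.
* Amplicon quantification consumes alignments; it does not align, trim
  primers, or reconcile read pairs.
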
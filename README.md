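# editscreen

Adenosine deamination by ADAR enzymes converts A to inosine (I) in
double-stranded RNA; reverse transcriptases and sequencers read inosine as
G, so editing shows up as an A→G signal in cDNA but not in genomic DNA.
`editscreen` is an R toolkit for studying such A-to-I(G) editing — with an
emphasis on 3'UTR editing in tumor/normal cohorts such as breast cancer —
aimed at computational biologists who have per-site editing-level matrices
from cohort RNA-seq, targeted amplicon resequencing data, and clinical
follow-up tables, and want a reproducible, tested path from those inputs
to differential-editing calls, feature annotation, validated editing
percentages, and survival stratification.

## What it computes

**Differential editing screen.** For a sites × samples matrix of editing
levels θ ∈ [0,1] with tumor/normal pairing metadata, a site is
*informative* when both members of at least `min_pairs` (default 5)
matched pairs are observed. Each informative site is tested with a
two-sided Wilcoxon rank-sum test of all tumor versus all normal values
(exact enumeration when both groups have n ≤ 8 and no ties; otherwise the
normal approximation with midrank tie correction and continuity
correction). P-values are adjusted by the Benjamini–Hochberg step-up,
q₍ᵢ₎ = min₍ⱼ≥ᵢ₎ p₍ⱼ₎·m/j, and a site is called significant when

    q < 0.05   and   |Δ| = |mean(tumor) − mean(normal)| ≥ 0.05 (5%),

with an `up_only` mode for screens focused on tumor-gained editing.

**Feature annotation and co-occurrence.** Sites are intersected with gene
models (GTF or BED12) and receive *all* overlapping labels from {5UTR,
CDS, 3UTR, exon, intron, ncRNA, upstream, downstream}, where the flanks
are the 1 kb strand-aware windows outside the transcription boundaries
and ncRNA marks transcripts without CDS; non-overlapping sites are
intergenic. Per gene, the exact set of edited feature classes is tallied
(the data behind an UpSet plot).

**Amplicon editing quantification.** From gDNA- and cDNA-templated PCR
amplicons sequenced in parallel (SAM input), every A position is piled up
(base quality ≥ 20, mapping quality ≥ 20) and scored as

    G% = 100 · G / (A + C + G + T).

A site must be genomically A (gDNA depth ≥ 100 and gDNA G% ≤ 1) and not a
known A→G SNP; it is called edited when cDNA G% ≥ 5. Sites off the a
priori candidate list are reported as novel discoveries, and condition
comparisons (e.g. ADAR1 knockdown vs control) report per-site differences
and fold changes.

**Survival and assay statistics.** Relapse-free survival records are
filtered to 0 < RFS ≤ 120 months, then stratified by the expression
cutoff minimizing the two-group log-rank p over all observed values in
the 10th–90th percentile ("auto select best cutoff"); the hazard ratio is
the Mantel–Haenszel estimate (O₂/E₂)/(O₁/E₁) with a log-scale CI from
1/E₁ + 1/E₂. Dual-luciferase (Firefly/Renilla, reference-normalized) and
densitometry (loading-control, reference-normalized) assays get one-way
ANOVA with Tukey HSD.

**Synthetic data.** Every input above can be generated with known truth:
beta-distributed cohort matrices with tumor shifts and missingness,
pre-aligned amplicon reads with injected editing and sequencing error, a
deterministic toy gene model with hand-computed probe expectations, and
bimodal-expression survival cohorts with a true hazard ratio.

## Worked example

```r
library(editscreen)

sim <- simulate_cohort_matrix(cohort_sim_spec(n_pairs = 100, n_sites = 1000,
                                              n_diff = 50, delta = 0.15,
                                              missing_rate = 0.1, seed = 1))
scr <- call_differential(sim$matrix, fdr_q = 0.05, min_delta = 0.05,
                         min_pairs = 5)
summary(scr)
#> sites: 1000  testable: 1000  significant: 50 (50 up / 0 down)
#> median delta among significant: 0.15

table(called = scr$results$significant,
      truly_differential = sim$truth$is_diff[match(scr$results$site_id,
                                                   sim$truth$site_id)])
#>        truly_differential
#> called  FALSE TRUE
#>   FALSE   950    0
#>   TRUE      0   50
```

All 50 sites whose tumor editing level was shifted by +0.15 are
recovered, with no false calls among the 950 null sites: at this effect
size the rank-sum test is saturated, and the 5% mean-difference floor
screens out small-q/small-effect noise. Survival stratification on a
simulated bimodal cohort:

```r
surv <- simulate_survival_cohort(300, hr_true = 3, censor_rate = 0.2, seed = 1)
best_cutoff_scan(rfs_filter(surv$records))
#> best-cutoff stratification: cutoff 6.798 (high n=159, low n=122)
#>   log-rank chi2 40.428, p 2.04e-10; HR (high vs low) 2.22 (95% CI 1.69-2.92)
#>   note: p is the minimum over 225 candidate cutoffs and is anti-conservative
```

The chosen cutoff (6.8) falls between the expression modes at 4 and 8;
the HR estimate attenuates below the generating value of 3 because the
Gaussian mode overlap misassigns a few patients, and the printed caveat
reminds you that a min-p scan inflates significance.

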
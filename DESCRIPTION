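Package: editscreen
Title: Cohort-Scale Screening and Amplicon Quantification of A-to-I RNA
    Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying adenosine-to-inosine (A-to-I) RNA editing
    in paired tumor/normal cohorts: an informative-site filter and
    per-site Wilcoxon differential-editing screen with Benjamini-Hochberg
    false-discovery control and an effect-size floor; genomic feature
    annotation of editing sites (UTRs, CDS, introns, 1 kb flanks,
    noncoding RNA) with per-gene feature co-occurrence sets; G-percent
    editing quantification from gDNA- and cDNA-templated amplicon
    sequencing with genotype confirmation and SNP exclusion; relapse-free
    survival stratification by best-cutoff log-rank scanning with
    Mantel-Haenszel hazard ratios; and dual-luciferase and densitometry
    normalization with one-way ANOVA and Tukey HSD. A synthetic-data
    module generates every input the pipeline consumes so all stages are
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    Rsamtools,
    survival,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
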
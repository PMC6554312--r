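Package: hkascan
Title: HKA-Like Selective Sweep Scans from Windowed Diversity/Divergence Ratios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects candidate selective sweeps in reference-mapped diploid
    cohorts by contrasting windowed nucleotide diversity (theta, with the
    n/(n-1) small-sample correction) against per-site divergence of a
    designated genome from the reference (D, heterozygous sites weighted 0.5).
    Implements the full site filter stack for all-sites VCFs (depth floor and
    per-sample depth-quantile ceiling, variant QUAL, genotype quality,
    missingness, biallelic-only, window-level GC), non-overlapping or sliding
    window construction with a callable-length requirement, empirical p-value
    outlier calling on the theta/D ratio, gene-overlap annotation of
    significant windows, flanking-divergence counts for candidate genes,
    neutral-locus missingness filtering, and conversion of mutation-scaled
    coalescent parameters (theta, tau, m) to effective sizes, years, and total
    migration probabilities. A seeded synthetic-data generator produces
    reference FASTA, all-sites VCF, and truth intervals with known diversity,
    divergence, sweep, and artifact structure so every stage is testable
    without external genomes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    Rsamtools,
    rtracklayer,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
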
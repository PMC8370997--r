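Package: serpens
Title: Detecting and Classifying Parallel Selection in Autotetraploid
    Population Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting repeated (parallel) directional selection
    across replicated pairs of populations adapted to contrasting substrates,
    and for classifying the evolutionary source of each parallel candidate
    allele. Implements ploidy-aware ingestion of tetraploid VCF genotypes with
    depth and missingness filters, windowed Hudson FST outlier scans,
    nucleotide diversity and Tajima's D with per-site downsampling,
    fourfold-degenerate site extraction, multi-set candidate intersection
    tests, genotype-environment association with latent-factor confounder
    correction and q-value FDR control, and a composite-likelihood model of
    allele-frequency coancestry around selected sites that distinguishes
    independent de novo mutation from shared standing variation and migration.
    A synthetic-data module (a multivariate-normal frequency generator and a
    forward Wright-Fisher tetraploid simulator) reproduces the statistical
    structure the analysis assumes so the whole pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
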
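Package: popgenscan
Title: Windowed Population-Genomic Scans for Selection, Introgression and
    Genome Composition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative population genomics of
    multi-sample diploid variant calls: sliding-window nucleotide diversity,
    Tajima's D and heterozygosity scans; Weir-Cockerham FST with
    z-transformation and a top-quantile FST/diversity-ratio selective-sweep
    caller; frequency-based ABBA-BABA D-statistics with block-jackknife
    standard errors; isochore GC segmentation of a reference genome with
    variant-density correlation; an allele-frequency-differential screen with
    Pearson chi-squared tests; and pairwise r2 linkage-disequilibrium decay
    curves. Includes a Balding-Nichols cohort simulator with implanted
    selective sweeps, haplotype-tract introgression, mosaic recombination and
    GC-block-structured references, so every stage can be validated against
    known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
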
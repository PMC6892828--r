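Package: sweepscan
Title: Selection-Signature Scans from Two-Population Resequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Genome scans for positive selection from multi-sample VCF
    genotype data using two complementary window statistics: the weighted
    variance-based fixation index (F_ST) between two populations and the
    pooled heterozygosity (H_P) within each population, both computed in
    overlapping sliding windows, Z-transformed genome-wide, and subjected
    to outlier calling (top-fraction for ZF_ST, fixed threshold for ZH_P).
    Includes SNP filtering (depth, minor allele frequency, missingness,
    biallelic autosomal), candidate-gene annotation by interval overlap
    with a GTF, Manhattan-style plots of the Z tracks, a reproducible
    end-to-end pipeline, and a two-population diploid genotype simulator
    with planted selective sweeps for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
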
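Package: haplopin
Title: Haplotype-Specific Variant Prioritization at Disease Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for prioritizing candidate regulatory variants at
    disease susceptibility loci from haplotype-resolution sequence panels.
    Implements locus refinement from unphased control genotypes via pairwise
    D-prime linkage disequilibrium (EM haplotype-frequency estimation),
    extraction and normalization of variants from multiple sequence
    alignments with low-complexity masking, calling of variants unique to
    risk haplotypes, population-based exclusion through tag-SNP carrier
    classification, active-enhancer calling from H3K4me1/H3K27ac/DNase peak
    overlap, and allele-specific position-weight-matrix motif gain/loss
    scanning with an empirical false discovery rate. A seeded synthetic-data
    generator produces locus panels, genotype matrices, peak tracks and
    motifs with known ground truth so every stage is verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
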
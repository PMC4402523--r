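Package: basecomp
Title: Individual-Strand Base Composition as a Genome Phenotype
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing DNA base composition on a single strand at the
    genome, chromosome, polymorphic-site and mutation-site levels. Computes
    Chargaff second-parity (PR2) metrics for assembled sequences, derives a
    per-individual base-composition phenotype ([A], [C], [G], [T] fractions)
    from diploid genotypes at biallelic SNPs, runs linear and kinship mixed-model
    genome scans of that phenotype with Bonferroni and allele-switching
    significance thresholds, and tests annotation terms and DNA-repair gene
    lists for enrichment in windows around trait-associated SNPs. A bundled
    simulator generates populations diverged through a bottleneck under a
    strand-symmetric, AT-biased mutation spectrum, with optional causal
    bias-modifier loci and mutation-accumulation lines, so every analysis can
    be exercised end to end with recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    methods,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    Biostrings,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    GenomicRanges,
    withr
Config/testthat/edition: 3
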
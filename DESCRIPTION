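Package: ldcontrast
Title: Cross-Population Comparison of Regional Linkage Disequilibrium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies differences in regional linkage disequilibrium (LD)
    between population panels. Computes pairwise LD statistics (D, D', signed r,
    r squared), full regional LD matrices and focal-SNP LD profiles from VCF or
    HapMap-style genotype tables; summarises the dissimilarity of two
    populations' LD structure with the eigenvalue-based varLD score; assesses
    significance by Monte Carlo permutation of population labels with
    Bonferroni correction across population pairs; and supports haplotype
    analysis (EM haplotype frequency estimation, confidence-interval haplotype
    blocks, greedy tag-SNP selection). A Gaussian-copula simulator generates
    two-population haplotype panels with controlled allele frequencies and
    controlled LD divergence for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    png,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
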
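Package: sibphase
Title: Half-Sib Haplotype Phasing, Recombination Detection and Sire Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reconstructs the sire-origin block structure of paternal
    haplotypes in half-sib families from unphased biallelic SNP genotypes,
    without requiring the sire's genotype. Opposing homozygotes among the
    half-sibs identify loci where the sire is heterozygous; a forward memory
    vector walk partitions each offspring's chromosome into blocks inherited
    from one of the sire's two strands, validating candidate recombination
    events against downstream markers to reject genotyping errors. The block
    structure is used to impute the sire's haplotypes and genotype and to
    phase every offspring into paternal and maternal haplotypes. Includes a
    truth-tracked forward-in-time population simulator for livestock-style
    half-sib designs, evaluation metrics (orientation-matched R-squared,
    switch error rate, imputation yield), diagnostic recombination summaries
    and block-image plots, and readers/writers for genotype matrices, PLINK
    PED/MAP, phased-haplotype TSV and VCF.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
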
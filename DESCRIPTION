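Package: sibtdt
Title: Family-Based Association and Genotype-Quality Workflows for Full-Sib Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for family-based genetic association analysis in large
    full-sib families, as used in aquaculture QTL mapping. Implements
    Mendelian-error masking, minor-allele orientation, segregation-distortion
    (extreme genotype ratio) filters, family merging with parental masking,
    the transmission disequilibrium test (TDT) for a binary trait with
    Bonferroni genome-wide significance, and genotype-imputation accuracy
    metrics (concordance, non-reference discordance, dosage r-squared)
    comparing an imputed call set against array truth. Includes a full-sib
    family simulator with sex-specific recombination, a partially penetrant
    sire-derived risk haplotype, and array-like and imputation-like
    observation models, so the entire pipeline can be exercised end-to-end
    on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
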
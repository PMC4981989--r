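Package: cnvgwas
Title: Multi-Cohort Copy Number Variant Genotyping and Quantitative
    Trait Association from SNP Array Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures common copy-number-variant (CNV) genotypes from SNP
    genotyping array intensity data (Log R Ratio or summed X+Y
    intensities) across multiple cohorts and platforms, and tests them
    for association with quantitative lung-function traits.  Provides
    sample quality control (intensity-noise filtering, ancestry
    principal-component outlier removal), per-region intensity
    summarization, EM Gaussian mixture clustering with BIC class-number
    selection and fixed-K re-clustering, cross-cohort harmonization by
    chi-square class-frequency compatibility against a reference cohort,
    copy-number-dose linear and GEE family association, inverse-variance
    and sample-size-weighted Z-score meta-analysis, tag-SNP linkage
    disequilibrium, and replication against external summary statistics.
    A synthetic multi-cohort study generator emulating the assumed
    statistical structure makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    mclust,
    metafor,
    sandwich,
    vcfR
Config/testthat/edition: 3
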
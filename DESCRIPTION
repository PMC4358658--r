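Package: twinprot
Title: Variance Decomposition and cis-pQTL Mapping for Longitudinal Twin
    Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing plasma protein abundance in longitudinal
    twin cohorts. Provides a synthetic-cohort generator with a known
    variance structure (monozygotic and dizygotic pairs sampled at two
    visits, cis-SNP genotypes, peptide-level intensities with
    abundance-dependent missingness), peptide-to-protein quantification
    with consistency filters and top-3 summarisation, maximum-likelihood
    decomposition of each protein's variance into heritable, common
    environment, individual environment, longitudinal and residual
    components under a kinship-structured multivariate-normal model, and a
    cis protein quantitative trait locus (pQTL) scan with permutation-based
    empirical p-values, cross-visit Fisher combination and Storey q-value
    false discovery control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    optparse
Config/testthat/edition: 3
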
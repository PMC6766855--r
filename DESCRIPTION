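Package: poolscan
Title: Pooled Exome-Wide Association Scanning for Insecticide Resistance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled-library (Pool-seq) exome scans that
    contrast insecticide-resistant and susceptible mosquito pools. Implements
    the site-selection cascade (per-library depth window, replicate
    heterogeneity chi-square concordance, cross-group intersection,
    polymorphism call), pooled contingency chi-square association with
    per-chromosome Benjamini-Hochberg false discovery rate control, codon-aware
    SNP annotation against GFF3 gene models, expected-heterozygosity
    selective-sweep diagnostics, gene-category polymorphism enrichment by
    exact Fisher tests, and pool-versus-genotype allele-frequency validation.
    A forward simulator of the pooled study design (causal resistance locus,
    linked sweep markers, genotype-dependent survival, replicate pools,
    overdispersed sequencing depth and base miscalls) provides ground truth
    for power and error-control studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
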
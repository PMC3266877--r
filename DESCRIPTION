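Package: slepipe
Title: eQTL-Integrated GWAS Discovery Pipeline for Systemic Lupus Erythematosus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged case-control association workflow for systemic lupus
    erythematosus (SLE) susceptibility mapping that integrates cis-eQTL
    evidence into candidate-SNP prioritization. Provides genotype and sample
    quality control (call rates, exact Hardy-Weinberg tests, identity-by-descent
    relatedness, PCA ancestry outliers, genomic control), Cochran-Armitage
    trend tests with allelic odds ratios, Mantel-Haenszel meta-analysis across
    replication stages, cis-eQTL regression with FDR-based positivity flags,
    compound GWAS+eQTL selection thresholds with pooled-DNA scan
    cross-referencing, and allele-specific transcript quantification (ASTQ)
    calibrated by genomic-DNA mixture standard curves. A synthetic-data module
    generates genotype, phenotype, expression, pooled-scan and qPCR datasets
    with the statistical structure the analysis assumes, so the whole pipeline
    is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    digest,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
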
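Package: hrdex
Title: Transcriptome-Based Homologous Recombination Deficiency Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies homologous recombination deficiency (HRD) from
    tumour transcriptomes. Counts genomic scars (loss of heterozygosity,
    large-scale state transitions, telomeric allelic imbalance) from
    allele-specific copy-number segments; trains an elastic-net regression
    of the scar score on gene expression with bootstrap stability selection
    to derive signed HRD gene signatures; and scores individual samples
    n-of-1-style with a signed single-sample enrichment statistic (expHRD)
    calibrated back to the scar scale with 95% prediction intervals.
    Includes a synthetic-data generator with planted scar events and a
    planted latent HRD signal so the full pipeline is testable without
    external cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
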
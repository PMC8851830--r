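Package: varcontact
Title: Linking Non-Coding GWAS Variants to Regulatory Elements Through the 3D Genome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links disease-associated non-coding variants from genome-wide
    association studies to gene-regulatory elements and their target genes,
    either through the linear genome (resolution-sized windows around each
    variant) or through the three-dimensional genome (statistically
    significant binned Hi-C contacts and topologically associating domains).
    Provides binomial significance calling for binned contact counts with
    Benjamini-Hochberg correction over equal-occupancy distance strata,
    one-fragment-per-variant contact selection, disease-association score
    aggregation (medians, disease-associated-TF fractions, quantile/IQR
    summaries), TopDom-style TAD detection with SNP-rich versus control
    stratification, and a seeded synthetic-data generator with recorded
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
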
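Package: famvarnet
Title: Family-Based Exome Variant Prioritization and Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("famvarnet", "developers", email = "famvarnet@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for family whole-exome studies of complex
    disease susceptibility, built around a venous-thromboembolism candidate
    gene panel workflow. Reads multi-sample VCF, PED pedigrees, gene panels
    and per-variant annotation tables; applies low-frequency (MAF) and
    quality filters with segregation analysis across affected members
    (carrier matrices, shared-in-affected sets, linkage/compound
    heterozygous groups); categorizes multi-tool deleteriousness predictions,
    ranks variants by REVEL, and applies rule-based prioritization joining
    eQTL/sQTL and ClinVar evidence; infers per-patient protein interaction
    networks from channelized evidence scores combined by a prior-corrected
    noisy-OR with confidence tiers, and performs hypergeometric term
    enrichment with Benjamini-Hochberg FDR. Includes a synthetic family
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    methods,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
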
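Package: rootdge
Title: Digital Gene Expression Analysis of Salinity Responses Across Maize
    Root Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a classic single-library digital
    gene expression (DGE) workflow for comparing salinity responses across
    maize primary, crown and seminal roots. Provides FASTQ clean-read
    filtering (adaptor, N-content and base-quality rules), RPKM
    quantification, an exact between-library differential-transcription
    test with false discovery rate adjustment and log2-ratio calling,
    cross-root-type set summaries, hierarchical clustering of log-ratio
    profiles with missing-expression handling, GO-term over-representation
    with Bonferroni correction, and delta-delta Ct qPCR concordance.
    Includes synthetic-data generators with planted ground truth so the
    whole pipeline can be exercised and validated at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
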
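Package: neoscreen
Title: Neoantigen Discovery from Somatic Missense Variants with
    Consensus MHC Class I Binding Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An immunogenomics pipeline for prioritizing candidate tumor
    neoantigens from somatic missense variants. Mutant peptide windows
    overlapping each altered residue are enumerated for MHC class I alleles
    (e.g. the murine H-2Kb and H-2Db), scored with additive position-specific
    scoring matrices that predict log10 IC50, combined across predictors into
    a consensus IC50, ranked by the affinity score (1/IC50)*100, filtered for
    transcript-level expression evidence, and extended into synthetic long
    peptides for vaccine design. A companion differential-expression stage
    quantifies transcripts per million (TPM) from counts and effective
    lengths, tests log-transformed expression between treatment groups with
    two-sample t-tests, applies Benjamini-Hochberg correction, and summarizes
    temporal induction across time points. A seeded synthetic-data generator
    produces every input the pipeline consumes, including a planted
    high-affinity neoepitope for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    GenomicRanges,
    ggplot2,
    optparse,
    SummarizedExperiment,
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
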
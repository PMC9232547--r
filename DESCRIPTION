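Package: apobecscope
Title: APOBEC Mutational-Process Analysis of Somatic SNV Catalogs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the APOBEC mutational process in somatic
    single-nucleotide-variant catalogs: trinucleotide-context spectra and
    COSMIC-style signature deconstruction by forward selection with
    golden-section refinement, tCw/CC motif-enrichment scoring and sample
    classification, kataegis (clustered hypermutation) detection and
    classification from intermutational distances, paired-catalog subtraction
    for control versus overexpression designs, and expression-stratified
    survival comparison with maximally selected log-rank cutpoints. A
    synthetic-data module generates ground-truth cohorts (reference sequence,
    signature-mixture catalogs with injected kataegis showers, paired cell-line
    catalogs, expression and survival tables) so every stage is testable
    without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
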
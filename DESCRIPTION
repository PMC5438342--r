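Package: regulonexo
Title: Transcription-Factor Regulon Reconstruction from ChIP-exo and Knockout RNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs a bacterial transcription-factor regulon by calling
    reproducible binding peaks from strand-specific ChIP-exo 5'-border
    profiles, discovering the binding motif by expectation-maximization,
    calling differential expression between wild-type and knockout strains
    from integer counts, and integrating binding with expression into a
    causally classified regulon (activated, repressed, not determined).
    Includes comparative analyses (cross-regulon overlap, functional and
    localization tabulation, ortholog conservation, growth-rate estimation)
    and a fully deterministic synthetic-data generator with planted ground
    truth so every stage is testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
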
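Package: trfid
Title: Digital T-RFLP Fingerprints and T-RF Affiliation from 16S rRNA
    Amplicon Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates digital terminal-restriction fragment length
    polymorphism (dT-RFLP) fingerprints from 16S rRNA amplicon sequencing
    reads by in-silico restriction digestion, aligns them to experimental
    T-RFLP (eT-RFLP) electropherogram profiles by cross-correlation to
    estimate and correct electrophoretic drift, and assigns taxonomic
    affiliations with per-phylotype contribution statistics to each
    terminal-restriction fragment. Includes quality filtering and greedy
    identity clustering of reads, exhaustive Smith-Waterman best-hit
    mapping against a taxonomy-annotated reference database, restriction
    enzyme screening with richness and Shannon diversity reports, and a
    seeded synthetic-community generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
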
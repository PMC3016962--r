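Package: estprofiler
Title: Electronic Spatio-Temporal Gene Expression Profiles from EST Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Turns dbEST-style Expressed Sequence Tag (EST) records into
    electronic spatio-temporal gene-expression profiles. Parses EST metadata
    from FASTA deflines or flat "EST Source" text, normalizes tissue,
    developmental-stage, sex and strain annotations against controlled
    vocabularies, resolves UniGene-style cluster tables to per-gene EST sets,
    computes transcripts-per-million (TPM) expression over tissue, stage and
    (tissue, stage) pools, classifies genes as ubiquitous, tissue-specific,
    stage-specific or mixed, and rolls BLASTx best-hit protein annotations up
    into Gene Ontology category summaries across datasets. A seeded synthetic
    data generator produces all input formats with machine-readable truth
    tables, so the whole pipeline is testable without any download.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    digest,
    igraph,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
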
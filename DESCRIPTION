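Package: pdblake
Title: Section-Wise Extraction and Fuzzy Distance Analysis of PDB
    Macromolecular Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Local batch extraction of macromolecular data from Protein
    Data Bank (PDB) format v3.3 text files, plain or gzip-compressed.
    Provides fixed-width parsers for the ATOM, HETATM, SHEET, HELIX and
    SEQRES sections; a "sequential file" store that concatenates many PDB
    entries into larger files delimited by END records, with a per-record
    size cap and streaming iteration; a deterministic parallel extraction
    engine with CSV output; an analysis of consecutive C-alpha distances
    per protein chain filtered by a Gaussian fuzzy condition "around
    3.81 Angstroms"; a seeded synthetic polypeptide generator for
    self-contained testing; and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    parallel,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
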
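Package: finishassay
Title: Finishing-Effort Assay for Shotgun Genome Sequence Assemblies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Standardized assessment of the effort required to finish
    shotgun-generated genome sequence assemblies. Aligns draft
    (comparative-grade) contigs to finished (human-grade) reference
    sequences, catalogues sequence gaps, classifies gaps as captured or
    uncaptured from plasmid read-pair evidence, profiles the GC and
    repeat-class composition of gap sequence, and scores per-contig
    variation in sequence-read redundancy. Includes a self-contained
    shotgun/assembly simulator for BAC-sized templates with interspersed
    and simple repeats, GC-rich islands, and a region-specific
    subclone-viability (cloning-bias) model for standard versus
    copy-control bacterial hosts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
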
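Package: contigscape
Title: Scriptable Exploration of Assembled Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for exploring assembled metagenomes from the command line
    or from scripts: ingestion and validation of per-contig metadata tables
    with sequence (FASTA) and annotation (GFF3) attachments, collapse of
    complete taxonomic lineages to a bounded set of legend groups, full-text
    search across metadata and annotations, numeric range filters, GC-by-
    coverage genome-bin gating, deterministic color schemes (ordinal,
    quantile-binned, gradient), declarative bubble-plot and contig-track
    specifications rendered to standalone interactive HTML, subset export
    (CSV, GFF3, FASTA), and a seeded synthetic-assembly generator for
    testing whole pipelines without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
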
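Package: renseqr
Title: Long-Read RenSeq Curation, Capture Assessment and Novel NLR Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for targeted capture enrichment (RenSeq) experiments
    sequenced on long-read platforms (Oxford Nanopore 2D-style or PacBio
    read-of-insert-style data). Implements pre-assembly read curation (fixed
    end trimming, approximate adapter removal, length filtering and
    chimeric-read removal), on-target capture-rate determination against a
    bait set, read and assembly quality statistics, a configurable NLR
    (nucleotide-binding leucine-rich repeat) protein motif classifier with
    six-frame translation, best-hit assembly evaluation against an annotated
    reference gene set, and an empirical-threshold triage procedure that
    flags reads likely to originate from novel NLR genes and scores their
    recovery after reassembly. A deterministic synthetic-data generator
    emulating paralogous NLR gene families, tiled capture baits, indel-rich
    platform error profiles, adapter-decorated reads and PCR chimeras makes
    the whole pipeline runnable and testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
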
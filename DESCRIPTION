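Package: methreprog
Title: Methylome Reprogramming Analysis for Human Gametes and Preimplantation Embryos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for downstream analysis of whole-genome bisulfite
    methylomes across gametes, blastocysts and somatic cells: parsing of
    Bismark-style cytosine reports and coverage files, CpG-dyad strand
    merging and depth filtering, fixed-CpG-count sliding-window
    classification of methylation changes with Benjamini-Hochberg
    correction, gamete-specific region categorisation, imprinted
    germline-DMR taxonomy, repeat-family and VNTR
    demethylation-protection screening, gene-body methylation versus
    expression integration, and a passive (replication-dependent)
    demethylation model. Includes a synthetic-methylome generator with
    planted ground truth so every stage is verifiable without access to
    controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
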
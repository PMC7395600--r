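Package: taxobridge
Title: Taxon-Concept Curation and Translation Across Monitoring-Program
    Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Curation system for reconciling species checklists used by
    regional biodiversity monitoring programs. Each program checklist is
    linked to an authoritative base list and, through it, to a master
    "switchboard" of fine-grained taxon concepts, all encoded as Darwin Core
    style parent/child taxon records in a single mapping file. On top of that
    graph the package aligns checklists and classifies their discrepancies
    (genus, species, spelling, conglomerate, unmatched), translates any taxon
    name from a receiver program into its equivalent(s) at a donor program
    with a compatibility label (perfect, compatible, multiple, lumped,
    absent) and warning flags, and builds species-concept integration
    matrices for whole species complexes. Ships the Celastrina ladon complex
    curation as a worked fixture and a synthetic checklist-network generator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
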
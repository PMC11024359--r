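Package: rtkclass
Title: Motif-Based Classification of Crustacean Receptor Tyrosine Kinases
Version: 0.1.0
Authors@R:
    person("rtkclass", "maintainers", email = "rtkclass@example.org",
           role = c("aut", "cre"))
Description: Degenerate consensus-motif scanning, supervised group-conservation
    motif discovery, and hierarchical class/subtype assignment for crustacean
    receptor tyrosine kinases (InsR, EGFR, FGFR, PVR). Ships the published
    class- and subtype-diagnostic motif library, locates the shared kinase
    landmarks (glycine-rich loop, catalytic loop, DFG), checks calls against
    extracellular domain architectures, and includes a synthetic protein-family
    generator with planted motifs so every stage is testable without a
    transcriptome database.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
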
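Package: glycopull
Title: E-Selectin Affinity Glycoproteomics Curation and Target Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating E-selectin affinity-pulldown glycoproteomics
    experiments aimed at sialylated Lewis antigen carriers. Provides glycan
    composition parsing and monoisotopic delta-mass arithmetic, chymotryptic
    in-silico digestion, a transparent glycopeptide precursor matcher with
    oxonium-ion validation, differential curation against IgG and
    calcium-depletion controls, N-/O-linkage partitioning, and an additive
    Target Score that ranks candidate glycoproteins by cancer association,
    prognosis, membrane localization and healthy-tissue expression. A
    synthetic-data module generates ground-truth-bearing FASTA, MGF, manifest
    and annotation bundles so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
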
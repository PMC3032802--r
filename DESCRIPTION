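Package: alup53
Title: p53 Binding Sites in Alu Repeats: PWM-20 Scanning, Repeat Mapping
    and Chromatin Context
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing p53 binding sites embedded in Alu
    repeats. Builds the symmetric, spacer-aware PWM-20 position weight
    model for 20-bp p53 sites (two RRRCWWGYYY decamers with dinucleotide
    terms at the CWWG cores), scans FASTA sequences for candidate sites
    over a range of spacer lengths with masking support, projects hits
    into repeat-consensus coordinates via RepeatMasker annotations and
    classifies the Box A/B/A' hotspots, quantifies CpG-deamination
    (CG to TG) footprints of functional response elements against Alu
    consensus sequences with a deterministic global aligner, models
    rotational nucleosome positioning of the right Alu monomer, and
    generates synthetic Alu-decay genomes with truth tables so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
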
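Package: pepdock
Title: Protein-Peptide Docking with Single-Chain Structure Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a protein-peptide docking protocol built around a
    single-chain structure predictor: the receptor and peptide sequences are
    fused with a flexible polyglycine linker, sampling diversity is obtained
    by randomly masking input residues, peptide placement is refined by
    adaptive recycling, candidate models are ranked by pLDDT-based confidence
    schemes, clearly misdocked models are filtered out, and model quality is
    assessed against native complexes with the CAPRI-derived DockQ score
    (FNAT, iRMSD, LRMSD). A deterministic synthetic backend and fixture
    generator make the whole protocol testable without GPU inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
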
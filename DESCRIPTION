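Package: molsculpt
Title: Seed-Molecule Derivative Generation by Monte Carlo Tree Search over SMILES
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hit-to-lead style molecular optimization that edits the SMILES
    string of a seed molecule rather than generating molecules from scratch.
    Partial SMILES fragments are proposed by a recurrent (two-layer LSTM)
    next-token policy trained on substrings of a reference corpus, spliced
    into the seed at positions chosen by an upper-confidence-bound Monte
    Carlo tree search, and scored with user-selectable objectives (QED,
    penalized logP, similarity-constrained penalized logP, or any callable
    registered by name).  Includes the "Single" (fixed seed) and "Multi"
    (seed replaced each cycle by the best molecule so far) outer protocols,
    evaluation metrics (validity, uniqueness, novelty, constrained-improvement
    summaries), a deterministic fixture-corpus generator, and a command-line
    interface.  Molecular parsing, descriptors and fingerprints are delegated
    to an RDKit worker process.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
SystemRequirements: Python (>= 3.8) with the rdkit package, used as a
    subprocess for SMILES parsing, descriptors and fingerprints.
Config/testthat/edition: 3
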
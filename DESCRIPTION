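Package: nbsevol
Title: Comparative Evolution of NBS-Encoding Resistance Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of plant NBS-encoding (NB-ARC,
    Pfam PF00931) disease-resistance gene families across related genomes:
    domain-architecture and subclass (TNL/CNL/RNL) classification from
    domain calls and diagnostic motif residues, chromosomal tandem-cluster
    assignment under a configurable distance rule, duplication-loss
    parsimony reconciliation of gene trees against a species tree with
    per-branch gain/loss ledgers and ancestral copy-number bookkeeping,
    simplified collinearity-block detection for typing duplications as
    tandem, ectopic or segmental, cross-genome locus-conservation classes,
    and a birth-death gene-family simulator with complete ground-truth
    event logs for validating every step.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
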
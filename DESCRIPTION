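Package: degeprimer
Title: Degenerate Group-Specific Primer Design and In-Silico Amplicon Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for designing group-specific degenerate marker-gene
    primers (e.g. 16S rRNA primers for lactic acid bacteria) and evaluating
    them in silico. Discovers conserved windows in a multiple alignment,
    emits degenerate primer candidates under length and degeneracy
    constraints, assembles pairs with a minimum product size, performs
    IUPAC-aware in-silico PCR with a 3'-anchor mismatch policy, scores
    amplicon-region species discriminability (pairwise identities,
    neighbor-joining trees, indistinguishable-pair fractions), and
    summarises amplicon surveys (subsampling, exact dereplication to OTUs,
    best-match taxonomy, target-read proportions, Shannon diversity,
    rarefaction). Includes a seeded synthetic-clade generator with planted
    primer sites so the whole pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    vegan,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
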
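Package: trpa1evo
Title: Domain-Partitioned Molecular Evolution of Vertebrate TRPA1
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative molecular-evolution analysis of
    the vertebrate thermosensor channel TRPA1. Implements maximum-likelihood
    pairwise distance estimation under the JTT amino-acid replacement model,
    neighbor-joining topology with Felsenstein-pruning maximum-likelihood
    branch lengths, domain-partitioned per-clade-group rate ratios (region
    versus full length), an alignment-anchored residue scan at the S5
    thermosensitivity position (human TRPA1 residue 878), and a clade-aware
    protein sequence evolution simulator that makes every stage testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
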
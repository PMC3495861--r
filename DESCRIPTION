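Package: phi6kp
Title: Known-Phylogeny Experimental Evolution of Bacteriophage phi6
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing 'known phylogeny' experimental
    evolution of the tri-segmented RNA bacteriophage phi6. Provides a
    forward-time simulator of bifurcating-deme serial passage with plaque
    growth, host-dependent selection with antagonistic pleiotropy, and
    fluctuating population bottlenecks; substitution classification through
    the genetic code and molecular-evolution statistics (per-segment
    substitution density, Ka/Ks tallies by treatment regime, Fisher exact and
    chi-square tests, reversion and parallel-mutation detection); in-package
    phylogenetic reconstruction (Fitch parsimony with exact branch-and-bound
    search, neighbor joining, site bootstrap, parsimony and marginal-likelihood
    ancestral states); scoring of inferred trees and ancestral sequences
    against the recorded truth; and competitive-fitness assay statistics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    phangorn,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
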
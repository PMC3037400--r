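Package: ssphylo
Title: Sequence-Structure Phylogenetics for ITS2 rRNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Joint sequence-secondary-structure phylogenetics for the
    internal transcribed spacer 2 (ITS2) and similar structured RNA markers.
    Nucleotide sequences and their dot-bracket secondary structures are
    encoded into a 12-letter joint alphabet, aligned globally with a
    sequence-structure scoring matrix (affine-gap Gotoh), and compared under
    a 12-state general time reversible (GTR) substitution model via
    maximum-likelihood pairwise distances.  Trees are reconstructed by
    Neighbor-Joining and Profile Neighbor-Joining with bootstrap support and
    outgroup rooting.  A continuous-time Markov chain simulator generates
    sequence-structure data with known history, a homology-transfer routine
    predicts a query structure from an annotated template, and a
    reproducible end-to-end pipeline ties the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phangorn,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
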
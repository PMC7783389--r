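Package: crfner
Title: Chemical and Gene/Protein Named Entity Recognition with
    Linear-Chain Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognition of chemical compound and gene/protein mentions in
    publication abstracts using linear-chain conditional random fields over
    orthographic, lexicon and part-of-speech token features.  Includes
    readers and writers for tab-separated standoff corpora (CHEMDNER-like
    and ChemProt-like dialects), offset-preserving word-punctuation
    tokenization, SOBIE span encoding and decoding, a natively implemented
    CRF (forward-backward likelihood and gradient, Viterbi decoding,
    L1/L2-regularised quasi-Newton training), chemical-type classification,
    token- and entity-level evaluation with macro averaging, k-fold
    cross-validation, candidate-inhibitor selection by type filtering and
    chemical-protein co-occurrence, literature name-profile differencing,
    and a synthetic annotated-corpus generator for fully offline training
    and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
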
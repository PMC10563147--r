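Package: ogmdesign
Title: Information-Theoretic Accuracy Modeling and Labeling-Pattern Design
    for Optical Genome Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models optical genome mapping (OGM) as a discrete memoryless
    channel over binned label counts and computes a closed-form
    finite-blocklength (normal-approximation) estimate of the fragment
    mapping error probability. Provides channel-parameter estimation from
    genome sequences and aligned bin-count data, Monte-Carlo validation
    with an exhaustive maximum-likelihood decoder over all genome offsets
    and both strand orientations, and exhaustive enumeration and ranking
    of candidate labeling patterns (including IUPAC-coded enzyme
    recognition sequences) for a target genome set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
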
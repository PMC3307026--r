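Package: causalsig
Title: Statistical Significance for Signed Causal Graph Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact and thresholded algorithms for the Ternary Dot Product
    Distribution, a generalization of Fisher's exact test to ternary
    (up/down/unchanged) classifications, together with uniform Markov-chain
    randomization of signed directed graphs preserving signed in- and
    out-degrees, simplicity and weak connectedness. These two null models
    support significance assessment of upstream-regulator hypotheses scored
    against differential-expression calls on a causal network: an exact
    p-value for the agreement score between predicted and observed
    regulation, and an empirical p-value over degree-preserving graph
    randomizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
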
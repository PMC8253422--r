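Package: specnull
Title: Spectral Estimation of Low-Dimensional Network Structure Against
    Generative Null Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects low-dimensional structure in weighted undirected
    networks by comparing the eigenspectrum of a comparison matrix
    C = W - <P> against bounds estimated by sampling networks from a
    generative null model (the full or sparse weighted configuration
    model). Data eigenvalues above the sampled upper bound (or below the
    lower bound) indicate community-like (or k-partite) structure and
    define a low-dimensional node projection; nodes whose projection does
    not exceed its null expectation are rejected, yielding a de-noised
    "signal" network that can be clustered by modularity-selected k-means
    or consensus clustering. Includes a weighted stochastic-block-model
    generator with an optional noise halo for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
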
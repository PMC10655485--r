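Package: dgdr
Title: Deep Generative Decoder Models of Bulk RNA-Seq for Single-Sample
    Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a decoder-only deep generative model of bulk RNA-seq counts
    in which every sample receives a learned low-dimensional representation,
    a Gaussian mixture model parameterizes the latent space, and a
    feed-forward decoder maps representations to gene-wise negative binomial
    distributions. For an unseen (e.g. tumor) sample the package infers the
    closest representation under the model of normal tissue and uses the
    resulting negative binomial distributions as an in-silico control for
    control-free, single-sample ("N-of-one") differential expression testing
    with an exact two-tailed count-level p-value, a fast grid approximation,
    fold-change and enrichment-score summaries. Includes a synthetic
    multi-tissue cohort generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
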
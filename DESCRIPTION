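Package: sdweat
Title: Bias Assessment for Word Embeddings with the WEAT and SD-WEAT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics for quantifying social bias in word embedding models.
    Implements the word embedding association test (WEAT): the cosine-based
    association measure, Cohen-style effect size, permutation test statistic,
    and the exact or Monte-Carlo p-value over equal-size partitions of the
    target union. Adds a resampling-based dispersion statistic (SD-WEAT)
    that pools the attribute sets, repeatedly redraws small random attribute
    subsets, and scores bias as the standard deviation of the resulting
    effect sizes, with significance calibrated by a random-vocabulary
    negative control and a right-tailed z-test. Includes readers for
    word2vec/GloVe text vector formats, a synthetic planted-bias embedding
    generator for validation, replicate-based stability analysis of
    embedding methods, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
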
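Package: phonorank
Title: Dirichlet Order-Statistics Models for Phoneme Rank-Frequency Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling the phoneme usage of texts. Converts
    plain text to phoneme counts through a pronunciation lexicon, ranks
    the resulting frequencies, and fits the ranked profile to the order
    statistics of a symmetric Dirichlet density with a single
    concentration parameter. Includes variational (total-variation)
    distances between phoneme frequency vectors, author-cluster gap
    statistics for stylometric comparison, a common-word ablation, and a
    seeded generator of synthetic Zipfian corpora with known author
    profiles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
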
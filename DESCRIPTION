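Package: litnav
Title: Navigating Related Biomedical Literature with Ranked Noun Phrases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts nouns, adjectives and noun phrases from the text of a
    paper, ranks them by contrasting in-document occurrence counts against
    background (web-scale) counts with a quantile-regression residual score,
    issues quoted exact-phrase searches over a document corpus, and evaluates
    each search term by citation validation: whether the top-20 results
    recover any of the paper's author-supplied citations, split into
    validation by the same authors (CV-S) or by entirely different authors
    (CV-D). Includes an analytic chance-validation null model, corpus-level
    summary statistics with binomial confidence intervals, and a synthetic
    corpus generator (Zipf background frequencies, topic-coherent citation
    graph, planted rare signature phrases) so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
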
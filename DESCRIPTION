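Package: littriage
Title: Automated Literature Triage for Product Risk Management
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ranks PubMed-style abstracts by the confidence that they are
    useful for pharmacovigilance / product risk assessment. Implements a
    text-mining chain (tokenisation, Porter stemming, stop-word removal,
    synonym merging, phrase detection), word-occurrence / binary / TF-IDF
    document-term weightings, four confidence-scoring classifiers (logistic
    regression, k-nearest neighbours, naive Bayes, Gaussian-kernel SVM),
    Kennard-Stone representative sampling, lift-chart and AUC evaluation,
    and the two composed deliverables: a drug-class-agnostic "general"
    automated system and a "specific" system bootstrapped from about 20
    freshly labelled abstracts. A synthetic-corpus generator with planted
    general and drug-class-specific signal supports benchmarking without
    any proprietary corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    e1071,
    methods,
    withr,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
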
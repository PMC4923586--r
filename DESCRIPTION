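Package: demotext
Title: Demographic Content Analysis of Health-Related Social Media Posts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lexicon-based content analysis of health-related social media
    posts stratified by author demographics. Provides health-keyword relevance
    filtering, tokenization with Porter stemming and a coarse rule-based
    part-of-speech tagger, SentiWordNet-style sentiment and NRC-style emotion
    scoring by greedy longest phrase match, dictionary-based medical-concept
    annotation with a misclassification blacklist and semantic-group
    restriction, demographic inference (first-name gender, surname ethnicity,
    Flesch-Kincaid writing level) with census-region and age binning, and the
    relative-difference statistic for extracting each demographic group's most
    distinctive terms, disorders and drugs. Includes a synthetic-corpus
    generator with planted term enrichments and lexicon-word injection so that
    every stage can be validated against closed-form ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    stringi,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
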
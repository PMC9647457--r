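Package: mednotesearch
Title: NLP-Enhanced Search over Clinical Free-Text Notes with
    Crossover-Study Evaluation Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Query expansion over a pluggable medical lexicon (synonyms,
    abbreviation short/long forms), fuzzy whole-word matching with a banded
    Levenshtein edit-distance policy and suffix-stripping stems, and a
    whole-word exact string-search baseline, applied to corpora of free-text
    patient notes with character-offset highlight spans and match provenance.
    Also provides the machinery to evaluate such search tools in a simulated
    clinical workflow: evidence-area marking of information-retrieval tasks,
    search-log metrics, group-imbalance weighting, and weighted paired
    two-tailed t-tests for three-arm crossover designs, together with a
    deterministic synthetic generator of clinical-style notes with planted
    misspellings, abbreviations and synonyms and gold annotations.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
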
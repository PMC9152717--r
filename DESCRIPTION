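Package: wikiread
Title: Multilingual Readability Analysis of Disease-Related Encyclopedia Corpora
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to harvest disease-related articles from an encyclopedia
    category graph, annotate them with ICD-10 codes via structured metadata
    and interlanguage links, score them with language-appropriate readability
    formulas (Flesch Reading Ease for English, German and Russian,
    Flesch-Kincaid Grade Level, Gunning FOG, SMOG, ARI, Coleman-Liau, and the
    fourth Wiener Sachtextformel), and compare readability across languages
    and ICD-10 chapters with Welch t tests and Holm adjustment. Includes a
    synthetic snapshot generator with controlled sentence-length, word-length
    and annotation structure so the whole pipeline can be exercised and
    validated without any network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
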
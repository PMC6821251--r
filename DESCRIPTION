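Package: dictannot
Title: Agile Dictionary-Based Annotation of Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and iteratively refining term dictionaries
    (lexicons of label-identifier pairs) and using them to annotate
    biomedical text with character-offset standoff annotations. Supports
    configurable exact and approximate matching (character n-gram cosine
    similarity with per-token stemming and Unicode folding), a JSON
    standoff interchange format, evaluation against reference annotation
    in precision/recall/F1 with exact-span and overlap disciplines,
    version diffing for regression testing, export of annotations as RDF
    triple statements with cross-project co-occurrence queries, a
    synthetic corpus generator with planted gold mentions, and a
    command-line workflow driving the revise-and-reannotate loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stringi,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
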
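Package: taxres
Title: Taxonomic Name Resolution: Normalization, Parsing, Fuzzy Matching
    and Free-Text Name Finding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for resolving scientific plant names
    against an integrated, Darwin-Core-style name backbone. Provides
    writing-form normalization of raw name strings, nomenclatural parsing
    (genus, epithets, rank markers, authorship, publication year), a
    cascading exact/fuzzy matcher based on per-token Levenshtein edit
    distance, whole-name detection in free text with character offsets,
    faceted name retrieval with autocomplete, a reproducible synthetic
    backbone generator, and a name-corruption benchmark protocol for
    measuring matcher recall.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    stringi,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
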
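Package: allerscreen
Title: In Silico Allergen Screening of Seed Proteomes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens a predicted seed proteome for allergen potential by
    mapping disease-linked linear epitopes (celiac disease and wheat
    allergy) onto protein sequences at a configurable windowed-identity
    threshold, simulating simultaneous gastrointestinal digestion with
    rule-based protease specificities (trypsin, pepsin at pH 1.3,
    chymotrypsin), calling epitope survival, filtering candidates by seed
    expression evidence from six-frame-translated EST local alignment, and
    characterising candidate sets by Gene Ontology over-representation
    (hypergeometric test with Benjamini-Hochberg FDR control). Ships a
    synthetic-data generator with a ground-truth manifest so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
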
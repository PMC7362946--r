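Package: ontolabel
Title: Selection and Harmonization of Translated Ontology Labels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rule-based curation of multilingual ontology label translations.
    Given several candidate translations per ontology term (e.g., Japanese
    labels for Human Phenotype Ontology terms drawn from dictionary-based,
    ontology-derived, expert and machine sources), the package selects a
    single preferable label per term by majority vote followed by an
    exclusion process that drops candidates showing anomalous morphological
    features (verbs, particles, adjectives, Japanese commas, untranslated
    Latin script, blanks). Competing candidate pairs are sub-classified as
    near-identical up to stop characters, word-order permutations, or
    divergent translations. Concept-equivalence pairs between two ontologies
    (e.g., HPO and the Mammalian Phenotype ontology) are classified on a
    two-by-two same/different grid over their English and translated labels
    and given harmonization recommendations, including a species-variant
    lexicon exception for labels that legitimately differ between human and
    animal usage. A seeded synthetic-fixture generator with gold token
    annotations makes the whole pipeline testable without any external
    morphological analyzer.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stringi,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
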
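---
title: "Rule-based curation of translated ontology labels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based curation of translated ontology labels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontolabel)
```

## The curation problem

Localizing a large phenotype ontology produces several competing
translations per term: dictionary-based lookups, labels inherited from a
related ontology, an expert's translations, and machine translation. Most
of these candidates are fine; a minority are sentence-like, half-translated
or empty. A curator cannot read tens of thousands of candidates, so
`ontolabel` automates the part that rules can decide — picking one
preferable label where the candidates agree or where all but one look
anomalous — and labels everything else with a precise reason for manual
review. A second workflow compares the localizations of two ontologies that
share concepts (such as a human and a mammalian phenotype ontology) and
recommends how to harmonize them.

## The selection decision list

For one term with candidates $c_1,\dots,c_m$ (one per source, possibly
empty), after normalization:

1. If every candidate is blank, the term is `BLANK`: there is nothing to
   choose from.
2. **Majority.** Over the non-blank candidates, a value with strictly
   largest multiplicity $\ge 2$ is chosen (`UNIQUE_MAJORITY`). Two distinct
   values each appearing exactly twice (and nothing higher) are a 2-2 tie
   (`TWO_CANDIDATES_MAJORITY`); with the standard four sources that is the
   only possible tie. With more sources, three-plus values tied at the top
   are treated as no majority and fall through. Blanks never vote: a blank
   is a missing translation, not a translation, so a 2-2 tie requires four
   non-blank candidates.
3. **Exclusion.** Remaining terms go to the anomaly stage. Each analyzable
   candidate is tokenized and scored for the six features below; any active
   feature excludes it. One survivor is chosen (`UNIQUE_EXCLUSION`); two or
   more distinct survivors are left for the curator
   (`MULTIPLE_EXCLUSION`); none means every candidate was anomalous
   (`NONE_EXCLUSION`).

The six outcomes are mutually exclusive and exhaustive, which the test
suite checks exhaustively over all 1,296 four-candidate configurations of
a six-label alphabet against an independently written restatement of this
list.

Majority runs before exclusion by default, which means a majority formed by
an anomalous label still wins — a known cost of the ordering. Because the
better ordering is a genuinely open question, `stage_order =
"exclusion_first"` is provided: it discards anomalous non-exempt candidates
first and then runs the same decision list on what is left, so a clean
minority can beat an anomalous majority.

### Exempt sources

Some sources (in the motivating setup, the dictionary-derived LSD
translation) produce labels that are concatenations of per-word dictionary
entries; a morphological analyzer systematically mis-segments them, so no
feature report exists for them. Exempt sources therefore participate in the
majority vote — string equality needs no analysis — but are invisible to
the exclusion stage: they can neither be excluded nor survive. The exempt
set is configuration, not a property of any particular source.

## Anomalous features

Ontology term labels should be noun phrases. Six features mark a candidate
as anomalous:

| feature | rule | needs tokens |
|---|---|---|
| `F1_VERB_OR_NONNOUN_END` | contains a verb, or final token is not NOUN/SUFFIX | yes |
| `F2_PARTICLE_OR_ADJVERB` | contains a particle or adjectival verb (na-adjective) | yes |
| `F3_ADJECTIVE` | contains a true adjective | yes |
| `F4_JA_COMMA` | contains 、 (U+3001) or ， (U+FF0C) | no |
| `F5_UNTRANSLATED_LATIN` | contains Latin letters (ASCII or fullwidth) | no |
| `F6_BLANK` | label empty after normalization | no |

Design choices behind the table:

* **A final suffix is noun-like.** Disease nouns ending in suffixes such as
  症 are perfectly normal term labels, so F1 accepts a trailing SUFFIX
  token. Whether word-final suffixes should count as non-noun endings is
  not decidable from first principles; this package decides they should
  not, consistent with treating 症 as near-meaningless in pair
  classification.
* **F4 includes the fullwidth comma** U+FF0C alongside the ideographic
  comma U+3001; both render as Japanese commas. The set is configurable.
* **F5 looks for Latin letters only.** Digits are common in legitimate
  labels (第1中足骨) and Greek letters are standard in biomedical
  nomenclature, so only an untranslated Latin-script word is flagged.
* **Features are separable.** Every feature is recorded as its own label
  and an `active` set restricts the report, so the exclusion criteria can
  be changed without re-running the analysis. The suite verifies that
  running with a restricted `active` set equals post-hoc filtering of the
  full report.
* A blank candidate carries `F6` and nothing else: emptiness pre-empts any
  other judgement.

## Normalization

All equality tests (voting, harmonization) run on normalized labels:
Unicode NFKC (halfwidth katakana to fullwidth, fullwidth Latin and digits
to ASCII, ideographic space to space), whitespace trimmed and internal runs
collapsed to one ASCII space. One deliberate exception: NFKC folds the
fullwidth comma U+FF0C into an ASCII comma, which would erase exactly the
signal F4 looks for. The Japanese comma codepoints are therefore shielded
from NFKC (configurable via `preserve`). Normalization is idempotent,
which the suite checks on random mixed-script strings.

## The tokenizer contract

The feature rules are stated over a closed coarse POS set — NOUN, VERB,
ADJECTIVE, ADJECTIVAL_VERB, PARTICLE, SUFFIX, SYMBOL, OTHER — rather than
any analyzer's native tagset, so analyzers are swappable. Two adapters
ship:

* `fixture_tokenizer(gold_table)`: deterministic lookup of pre-annotated
  token sequences with a single-NOUN fallback for unknown strings. All
  tests and synthetic runs use it; it needs nothing installed.
* `mecab_tokenizer()`: a thin shell-out to an external MeCab-compatible
  analyzer, with an optional user dictionary (a medical-term dictionary
  markedly improves segmentation of clinical labels) and a configurable
  native-to-coarse tag mapping (`map_pos()`, defaults covering
  IPADIC/UniDic top-level tags, unmapped tags to OTHER). It is optional
  and never exercised by the tests.

Every adapter output must satisfy the coverage invariant: token surfaces
concatenate to the analyzed string up to whitespace-only gaps.

## Pair sub-classification

Two competing candidates are classified as:

* `NEAR_IDENTICAL` — equal after stripping a trailing run of stop
  characters (default 症). Stripping is trailing-only: removing interior
  occurrences would merge genuinely different concepts (症状の記録 must
  not lose its first character). A label consisting wholly of stop
  characters is kept unchanged so stripping never empties a label.
* `PERMUTED` — not near-identical, but the multisets of token surfaces
  agree. This is a word-level notion (the candidates chose the same
  translated words in a different order), so it uses tokens, not bags of
  characters.
* `DIVERGENT` — the residual class. One side is usually a mistranslation,
  but deciding which would need semantic resources this package does not
  assume.

The classification is symmetric in its two arguments (property-tested).

## Harmonization across two ontologies

Given concept-equivalence pairs with English and translated labels on both
sides, exact post-normalization string comparison yields:

| category | action |
|---|---|
| `BOTH_SAME` | `KEEP` — nothing to change |
| `EN_SAME_ONLY` | `UNIFY_TO_A`, or `SPECIES_VARIANT_KEEP` (below) |
| `JA_SAME_ONLY` | `NO_CHANGE`, flagged `concept_similarity_not_checked` |
| `BOTH_DIFFERENT` | `MANUAL_CURATION` |
| `NO_JA_CANDIDATE` | `AWAIT_TRANSLATION` — a translation is missing |

Side "a" is the precedence side — the localization assumed to be in wider
use — and is a flag (`precedence_side`), not a property of either
ontology. No stop-character stripping is applied here: the grid is defined
as a character-string comparison, and a softer comparison can always be
layered on via `classify_pair()`.

**Species variants.** Terms for external morphology are legitimately
translated differently across species: male/female are 男性/女性 for
humans but オス/メス for mice or rats. Forcing precedence would erase
correct biology, so when only the English labels agree and a
species-variant lexicon explains the difference, both renderings are kept.
The check maps both labels to a canonical form (every animal form replaced
by its human form, longest form first — or symmetrically human to animal)
and compares; this contains the directed substitution reading and, unlike
it, is symmetric in the two labels no matter which side carries the animal
rendering. The default lexicon holds the two male/female pairs;
`read_species_lexicon()` loads a larger one.

`JA_SAME_ONLY` maps to `NO_CHANGE` unconditionally because concept
similarity is not operationalized here; the report carries a warning flag
so curators know the judgement was assumed, not computed.

## Synthetic fixtures and what they show

`generate_candidates()` and `generate_pairs()` build seeded tables in
which every term's outcome (and every pair's category) is planted by
construction: majority winners get the required multiplicity, exclusion
outcomes get exactly the required number of clean non-exempt candidates,
anomalous candidates carry one planted feature, and all labels within a
term are pairwise distinct. Labels are assembled from a pool of twenty
anatomical nouns with no prefix relations (so distinct leading nouns imply
distinct labels) plus planted verbs, particles, adjectives, commas and
Latin fragments; the gold token annotation of every generated label is
therefore correct by construction. Defaults: a uniform mix over the six
outcomes and five categories, a uniform feature mix, and a 0.5
species-variant rate among `EN_SAME_ONLY` pairs so both branches of the
species exception are exercised. The end-to-end suites run 500 terms and
400 pairs, sizes at which every outcome class appears dozens of times
while the whole suite stays fast.

What passing these runs shows: the decision list, feature logic and
harmonization grid are implemented exactly. What it does not show: anything
about real-world segmentation quality. Real candidate tables come with a
real analyzer whose tokenization errors (especially on clinical
compounds) propagate into F1–F3; the fixture generator deliberately
emulates label *structure*, not the statistics of real HPO labels or
analyzer noise. The gold annotations used for the worked verb-containing
example likewise annotate its function words as OTHER to isolate the
verb feature; a real analyzer would also emit particles there and flag F2
alongside F1.

## Numerical and degenerate-input choices

* Probability vectors in `fixture_spec()` must sum to 1 within $10^{-9}$.
* Voting equality is exact string equality after normalization — no fuzzy
  matching; anything softer belongs in pair classification.
* Ties in the majority stage beyond the 2-2 case (possible only with more
  than four sources) fall through to exclusion rather than guessing.
* Empty text tokenizes to an empty sequence, not an error; a missing token
  sequence for an analyzable candidate while token-level features are
  active is a contract error, never silently treated as clean.
* Reports are written in a tab-separated dialect with backslash escapes so
  that labels containing tabs or newlines round-trip field-exactly
  (property-tested); JSON mirrors are written next to summaries.
* Re-running any workflow on identical inputs produces byte-identical
  reports.

## Known limitations

* No semantic ranking among multiple clean survivors, and no attempt to
  detect which side of a `DIVERGENT` pair is the mistranslation.
* The species lexicon is a literal substitution table; it cannot express
  context-dependent variants.
* OBO reading extracts term ids and primary names only (no synonyms,
  no OWL).
* The `exclusion_first` ordering is provided as an alternative policy, but
  which ordering yields better curation outcomes on real data is an open
  empirical question.
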
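# ontolabel

Rule-based curation of multilingual ontology label translations.

When an ontology such as the Human Phenotype Ontology (HPO) is localized,
each term often ends up with several candidate translations from different
sources — a life-science dictionary, labels carried over from a related
ontology, an expert translator, machine translation. `ontolabel` is for the
curators of such localizations: it picks one preferable translation per term
where the evidence allows, flags the rest for manual review with a precise
reason, and classifies translation pairs shared between two ontologies
(e.g. HPO and the Mammalian Phenotype ontology, MP) so the two localizations
can be harmonized for cross-species phenotype matching.

## Method

**Label selection.** For a term with candidate labels
\(c_1, \dots, c_m\) (one per source, normalized by NFKC + whitespace
collapsing), the decision list is:

1. **Blank** — all candidates empty → `BLANK`.
2. **Majority** — over non-blank candidates, a value with strictly largest
   multiplicity ≥ 2 wins (`UNIQUE_MAJORITY`); a 2-2 tie between two values
   gives `TWO_CANDIDATES_MAJORITY`.
3. **Exclusion** — otherwise each analyzable candidate is morphologically
   tokenized and tested for six anomalous features: F1 contains a verb or
   ends in a non-noun word, F2 contains particles or adjectival verbs
   (na-adjectives), F3 contains adjectives, F4 contains a Japanese comma
   (、 or ，), F5 contains untranslated Latin script, F6 is blank. Ontology
   term labels should be noun phrases, so any active feature excludes the
   candidate. One survivor → `UNIQUE_EXCLUSION`; several →
   `MULTIPLE_EXCLUSION`; none → `NONE_EXCLUSION`. Sources whose entries are
   word-by-word dictionary combinations (the `exempt_sources`) vote but are
   not analyzed, so they neither get excluded nor survive.

**Pair sub-classification.** Two surviving candidates are
`NEAR_IDENTICAL` when they agree after trailing stop characters (default
症) are stripped, `PERMUTED` when their token-surface multisets agree
(same words, different order), else `DIVERGENT` (usually a mistranslation
on one side).

**Harmonization.** A concept-equivalence pair between two ontologies is
placed on a 2×2 grid by exact post-normalization equality of its English
and translated labels: `BOTH_SAME` → keep; `EN_SAME_ONLY` → unify to the
precedence side, unless a species-variant lexicon (男性/オス, 女性/メス, …)
explains the difference, which is a legitimate human/animal split
(`SPECIES_VARIANT_KEEP`); `JA_SAME_ONLY` → no change (with a curator
warning that concept similarity is assumed); `BOTH_DIFFERENT` → manual
curation; a missing translation on either side → `AWAIT_TRANSLATION`.

Every rule runs over a pluggable tokenizer adapter. A deterministic fixture
tokenizer (gold annotations + single-noun fallback) makes the whole
pipeline testable offline; an adapter for an external MeCab-compatible
analyzer with a user dictionary is provided but never required.

## Worked example

```r
library(ontolabel)

cs <- candidate_set("HP:0100785",
                    c("不眠", "不眠症", "睡眠が浅い", ""),
                    sources = c("LSD", "MP", "EXPERT", "MT"))
select_label(cs)
#> <selection_result HP:0100785: MULTIPLE_EXCLUSION [不眠症 | 睡眠が浅い]>
```

All candidates differ, so the decision falls to the exclusion stage. Under
the default configuration the LSD source is exempt (it votes but is not
analyzed), and the default tokenizer has no annotations, so both non-exempt,
non-blank candidates survive. With gold tokens (症 = suffix, が = particle,
浅い = adjective) the sentence-like candidate is excluded (F1/F2/F3) and a
unique label remains:

```r
tk <- fixture_tokenizer(list(
  "不眠"       = token_seq("不眠", "NOUN"),
  "不眠症"     = token_seq(c("不眠", "症"), c("NOUN", "SUFFIX")),
  "睡眠が浅い" = token_seq(c("睡眠", "が", "浅い"),
                           c("NOUN", "PARTICLE", "ADJECTIVE"))
))
select_label(cs, tk)
#> <selection_result HP:0100785: UNIQUE_EXCLUSION [不眠症]>
classify_pair("不眠", "不眠症", tk)
#> <pair_verdict: NEAR_IDENTICAL (不眠 vs 不眠)>
```

The pair verdict shows the dictionary label and the chosen label differ
only by the stop character 症, so the choice is safe.

A full synthetic run, end to end:

```r
cfg <- run_config(seed = 7)
paths <- run_simulate(cfg, n = 500, out_dir = "fixtures")
res <- run_select(cfg, paths$candidates, "report.tsv",
                  gold_path = paths$gold_tokens)
summarize_labels(res)
#> All terms                                   500
#> A unique translation                        152
#>   determined by a majority                  80
#>   determined by an exclusion process        72
#> Two appropriate candidates (majority)       80
#> Multiple appropriate candidates (exclusion) 105
#> No appropriate candidates (exclusion)       70
#> BLANK                                       93
```

The same commands are available from a shell via
`Rscript inst/cli/ontolabel.R {select|pairs|harmonize|simulate} …`.

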
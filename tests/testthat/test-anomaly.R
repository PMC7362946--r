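test_that("normalization unifies width, strips and collapses whitespace", {
  expect_equal(normalize_label("　不眠症 "), "不眠症")
  expect_equal(normalize_label(""), "")
  expect_equal(normalize_label("Ａｂｃ１"), "Abc1")
  expect_equal(normalize_label("ｱﾋﾟﾈ"), "アピネ")
  expect_equal(normalize_label("a  \t b"), "a b")
  # Japanese comma codepoints survive normalization
  expect_equal(normalize_label("心臓、転位"), "心臓、転位")
  expect_equal(normalize_label("心臓，転位"), "心臓，転位")
  expect_equal(normalize_label(NA_character_), "")
})

test_that("normalization is idempotent on random strings", {
  set.seed(5)
  labs <- random_labels(200)
  once <- normalize_label(labs)
  expect_identical(normalize_label(once), once)
})

test_that("string-level features fire without tokens", {
  r4 <- detect_features("異所性心臓、心臓転位")
  expect_equal(r4$features, "F4_JA_COMMA")
  expect_false(r4$analyzed)

  r5 <- detect_features("角膜 stromal 浮腫")
  expect_equal(r5$features, "F5_UNTRANSLATED_LATIN")

  r6 <- detect_features("")
  expect_equal(r6$features, "F6_BLANK")
  expect_true(is_anomalous(r4) && is_anomalous(r5) && is_anomalous(r6))
})

test_that("token-level features follow the POS rules", {
  tk <- gold_tk()
  lab <- "幅広い長管骨"
  r3 <- detect_features(lab, tokenize(lab, tk))
  expect_equal(r3$features, "F3_ADJECTIVE")
  expect_true(r3$analyzed)

  lab <- "尺骨の有力な茎状突起"
  expect_equal(detect_features(lab, tokenize(lab, tk))$features,
               "F2_PARTICLE_OR_ADJVERB")

  # a trailing suffix is noun-like, so a suffixed disease noun is clean
  lab <- "不眠症"
  expect_equal(detect_features(lab, tokenize(lab, tk))$features, character(0))

  # a final non-noun token triggers F1 even with no verb present
  ts <- token_seq(c("腎臓", "の"), c("NOUN", "PARTICLE"))
  feats <- detect_features("腎臓の", ts)$features
  expect_true(all(c("F1_VERB_OR_NONNOUN_END", "F2_PARTICLE_OR_ADJVERB")
                  %in% feats))
})

test_that("a blank label carries F6 and nothing else", {
  r <- detect_features("", tokens = NULL, active = anomaly_features())
  expect_equal(r$features, "F6_BLANK")
  # F6 absent when the label is non-empty, whatever else it contains
  r2 <- detect_features("心臓、a")
  expect_false("F6_BLANK" %in% r2$features)
})

test_that("missing tokens for an analyzable candidate is a contract error", {
  expect_error(detect_features("不眠", tokens = NULL, analyzable = TRUE),
               "tokens missing")
  # fine when token-level features are inactive
  expect_silent(detect_features("不眠", tokens = NULL, analyzable = TRUE,
                                active = c("F4_JA_COMMA", "F6_BLANK")))
})

test_that("feature separability: restricting active equals post-hoc filter", {
  tk <- gold_tk()
  set.seed(13)
  corpus <- c(names(gold_examples()), normalize_label(random_labels(60)))
  subsets <- list(
    "F4_JA_COMMA",
    c("F1_VERB_OR_NONNOUN_END", "F5_UNTRANSLATED_LATIN"),
    c("F2_PARTICLE_OR_ADJVERB", "F3_ADJECTIVE", "F6_BLANK"),
    anomaly_features()
  )
  for (lab in corpus) {
    toks <- if (nzchar(lab)) tokenize(lab, tk) else NULL
    full <- detect_features(lab, toks)$features
    for (s in subsets) {
      restricted <- detect_features(lab, toks, active = s)$features
      expect_identical(restricted, intersect(full, s))
    }
  }
})

test_that("appending a verb token never removes F1", {
  set.seed(17)
  for (rep in 1:25) {
    n <- sample.int(5L, 1L)
    surfaces <- sample(c("心臓", "肝臓", "の", "なる", "幅広い"), n,
                       replace = TRUE)
    pos <- sample(pos_tags(), n, replace = TRUE)
    ts <- token_seq(surfaces, pos)
    lab <- ts$source_text
    before <- detect_features(lab, ts)$features
    ts2 <- token_seq(c(surfaces, "なる"), c(pos, "VERB"))
    after <- detect_features(ts2$source_text, ts2)$features
    expect_true("F1_VERB_OR_NONNOUN_END" %in% after)
    if ("F1_VERB_OR_NONNOUN_END" %in% before) {
      expect_true("F1_VERB_OR_NONNOUN_END" %in% after)
    }
  }
})

test_that("string-level features are tokenizer-independent", {
  adapters <- list(fixture_tokenizer(), gold_tk())
  for (lab in c("異所性心臓、心臓転位", "角膜 stromal 浮腫", "心臓転位")) {
    feats <- lapply(adapters, function(tk) {
      intersect(detect_features(lab, tokenize(lab, tk))$features,
                c("F4_JA_COMMA", "F5_UNTRANSLATED_LATIN", "F6_BLANK"))
    })
    expect_identical(feats[[1]], feats[[2]])
  }
})
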
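# Shared gold token annotations and helpers for the test suite.

# Gold morphological annotations for the worked examples exercised in the
# tests. Function words inside the verb-bearing label are annotated OTHER so
# each example isolates a single feature class.
gold_examples <- function() {
  list(
    "不眠症" = token_seq(c("不眠", "症"), c("NOUN", "SUFFIX")),
    "異所性心臓、心臓転位" = token_seq(
      c("異所性", "心臓", "、", "心臓", "転位"),
      c("NOUN", "NOUN", "SYMBOL", "NOUN", "NOUN")),
    "角膜 stromal 浮腫" = token_seq(
      c("角膜", "stromal", "浮腫"), c("NOUN", "NOUN", "NOUN"),
      source_text = "角膜 stromal 浮腫"),
    "幅広い長管骨" = token_seq(
      c("幅広い", "長管骨"), c("ADJECTIVE", "NOUN")),
    "尺骨の有力な茎状突起" = token_seq(
      c("尺骨", "の", "有力な", "茎状突起"),
      c("NOUN", "PARTICLE", "ADJECTIVAL_VERB", "NOUN")),
    "出生時にみられ時間とともに真っすぐなる大腿骨湾曲" = token_seq(
      c("出生時", "に", "みられ", "時間", "とともに", "真っすぐ",
        "なる", "大腿骨", "湾曲"),
      c("NOUN", "OTHER", "VERB", "NOUN", "OTHER", "NOUN", "VERB",
        "NOUN", "NOUN")),
    "髄様甲状腺癌" = token_seq(
      c("髄様", "甲状腺", "癌"), c("NOUN", "NOUN", "NOUN")),
    "甲状腺髄様癌" = token_seq(
      c("甲状腺", "髄様", "癌"), c("NOUN", "NOUN", "NOUN")),
    "硬化症" = token_seq(c("硬化", "症"), c("NOUN", "SUFFIX")),
    "第1中足骨硬化症" = token_seq(
      c("第1中足骨", "硬化", "症"), c("NOUN", "NOUN", "SUFFIX"))
  )
}

gold_tk <- function() fixture_tokenizer(gold_examples())

# Random label strings over a mixed pool (Japanese, fullwidth forms,
# Latin, whitespace) for property-style tests.
random_labels <- function(n, max_len = 12L) {
  pool <- c(strsplit("心臓肝腎脾肺脳眼骨皮膚症炎腫の、，男性女性オスメス", "")[[1]],
            strsplit("ＡＢＣａｂｃABCabc019 ", "")[[1]], "　", "\t")
  vapply(seq_len(n), function(i) {
    paste(sample(pool, sample.int(max_len, 1L), replace = TRUE),
          collapse = "")
  }, character(1))
}

# A four-source candidate set over unnamed sources S1..S4.
cs4 <- function(labels, term_id = "T:1") {
  candidate_set(term_id, labels, sources = paste0("S", seq_along(labels)))
}

# Config with no exempt sources, for tests where all candidates are
# analyzable.
config_plain <- function(...) {
  run_config(sources = paste0("S", 1:4), exempt_sources = character(0), ...)
}
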
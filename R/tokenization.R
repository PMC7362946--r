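#' Coarse part-of-speech categories
#'
#' The closed set of coarse part-of-speech tags used throughout the package.
#' Anomaly rules are stated over grammatical classes (verbs, particles,
#' adjectives, adjectival verbs/na-adjectives), not over any analyzer's native
#' tagset, so every adapter maps its own tags onto this set.
#'
#' @return Character vector of the eight coarse POS tags.
#' @export
pos_tags <- function() {
  c("NOUN", "VERB", "ADJECTIVE", "ADJECTIVAL_VERB",
    "PARTICLE", "SUFFIX", "SYMBOL", "OTHER")
}

#' Construct a token sequence
#'
#' A `token_seq` holds the morphological segmentation of one label: token
#' surfaces, coarse POS tags, and the analyzed source text. The concatenation
#' of the surfaces must equal the source text up to whitespace-only gaps.
#'
#' @param surface Character vector of token surfaces (each non-empty).
#' @param pos Character vector of coarse POS tags, same length as `surface`;
#'   each must be one of [pos_tags()].
#' @param source_text The analyzed string. Defaults to the concatenation of
#'   the surfaces.
#' @param pos_detail Optional analyzer-native tag strings (informational).
#' @return An object of class `token_seq`.
#' @examples
#' token_seq(c("不眠", "症"), c("NOUN", "SUFFIX"))
#' @export
token_seq <- function(surface = character(),
                      pos = character(),
                      source_text = paste(surface, collapse = ""),
                      pos_detail = NULL) {
  surface <- as.character(surface)
  pos <- as.character(pos)
  if (length(surface) != length(pos)) {
    stop("`surface` and `pos` must have the same length", call. = FALSE)
  }
  if (any(!nzchar(surface))) {
    stop("token surfaces must be non-empty", call. = FALSE)
  }
  bad <- setdiff(unique(pos), pos_tags())
  if (length(bad)) {
    stop("unknown POS tag(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(pos_detail)) pos_detail <- rep("", length(surface))
  strip_ws <- function(x) stringi::stri_replace_all_regex(x, "\\s+", "")
  if (!identical(strip_ws(paste(surface, collapse = "")),
                 strip_ws(source_text))) {
    stop("token surfaces do not cover source_text: ",
         encodeString(source_text), call. = FALSE)
  }
  structure(
    list(surface = surface, pos = pos, pos_detail = as.character(pos_detail),
         source_text = source_text),
    class = "token_seq"
  )
}

#' @export
print.token_seq <- function(x, ...) {
  if (length(x$surface) == 0L) {
    cat("<token_seq: empty>\n")
  } else {
    cat("<token_seq:", paste0(x$surface, "/", x$pos, collapse = " "), ">\n")
  }
  invisible(x)
}

#' @export
length.token_seq <- function(x) length(x$surface)

#' Map an analyzer-native POS tag to the coarse tag set
#'
#' Total function: any tag not present in the mapping falls back to `OTHER`
#' (reported once per unseen tag via a message).
#'
#' @param native_tag Character vector of analyzer-native (top-level) POS tags.
#' @param mapping Named character vector, analyzer tag -> coarse tag.
#'   Defaults to [default_pos_mapping()].
#' @return Character vector of coarse POS tags.
#' @export
map_pos <- function(native_tag, mapping = default_pos_mapping()) {
  bad_target <- setdiff(unique(mapping), pos_tags())
  if (length(bad_target)) {
    stop("mapping targets outside the coarse POS set: ",
         paste(bad_target, collapse = ", "), call. = FALSE)
  }
  out <- unname(mapping[native_tag])
  unknown <- unique(native_tag[is.na(out)])
  for (tag in unknown) {
    if (!isTRUE(.ontolabel_state$warned_tags[[tag]])) {
      message("unmapped POS tag '", tag, "' mapped to OTHER")
      .ontolabel_state$warned_tags[[tag]] <- TRUE
    }
  }
  out[is.na(out)] <- "OTHER"
  out
}

.ontolabel_state <- new.env(parent = emptyenv())
.ontolabel_state$warned_tags <- list()

#' Default mapping from Japanese analyzer tags to coarse POS
#'
#' Covers the top-level tags of the common IPADIC/UniDic-style tagsets:
#' nouns, verbs, true adjectives, na-adjectives (adjectival verbs),
#' particles, suffixes and symbols. Everything else falls back to `OTHER`.
#'
#' @return Named character vector suitable for [map_pos()].
#' @export
default_pos_mapping <- function() {
  c(
    "名詞" = "NOUN",              # noun
    "動詞" = "VERB",              # verb
    "形容詞" = "ADJECTIVE",   # i-adjective
    "形容動詞" = "ADJECTIVAL_VERB", # na-adjective (IPADIC)
    "形状詞" = "ADJECTIVAL_VERB",       # na-adjective (UniDic)
    "助詞" = "PARTICLE",          # particle
    "接尾辞" = "SUFFIX",      # suffix (UniDic)
    "接尾" = "SUFFIX",            # suffix (IPADIC subtag style)
    "記号" = "SYMBOL",            # symbol
    "補助記号" = "SYMBOL" # supplementary symbol (UniDic)
  )
}

#' Build a deterministic fixture tokenizer
#'
#' Returns a tokenizer adapter backed by a gold table of pre-annotated token
#' sequences. Known (normalized) strings return their stored annotation;
#' unknown non-empty strings fall back to a single NOUN token spanning the
#' whole string; the empty string returns an empty sequence. This makes all
#' downstream rule logic testable with no morphological analyzer installed.
#'
#' @param gold_table Named list of `token_seq` objects, keyed by normalized
#'   label. May be empty (pure fallback tokenizer).
#' @return A function `(text) -> token_seq` usable wherever a tokenizer
#'   adapter is expected.
#' @examples
#' tk <- fixture_tokenizer()
#' tk("abc")  # single NOUN token
#' @export
fixture_tokenizer <- function(gold_table = list()) {
  if (length(gold_table)) {
    if (is.null(names(gold_table)) || any(!nzchar(names(gold_table)))) {
      stop("gold_table must be a named list keyed by label", call. = FALSE)
    }
    ok <- vapply(gold_table, inherits, logical(1), what = "token_seq")
    if (!all(ok)) stop("gold_table entries must be token_seq objects",
                       call. = FALSE)
  }
  force(gold_table)
  function(text) {
    stopifnot(is.character(text), length(text) == 1L)
    if (!nzchar(text)) return(token_seq())
    hit <- gold_table[[text]]
    if (!is.null(hit)) return(hit)
    token_seq(surface = text, pos = "NOUN", source_text = text)
  }
}

#' Tokenize a normalized label through an adapter
#'
#' Thin validating wrapper around a tokenizer adapter: empty input yields an
#' empty sequence (not an error); adapter output is checked against the
#' `token_seq` invariants; adapter failures are re-raised naming the
#' offending text.
#'
#' @param text A single normalized label string (see [normalize_label()]).
#' @param analyzer A tokenizer adapter, e.g. from [fixture_tokenizer()] or
#'   [mecab_tokenizer()].
#' @return A `token_seq`.
#' @export
tokenize <- function(text, analyzer = fixture_tokenizer()) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(token_seq())
  out <- tryCatch(analyzer(text), error = function(e) {
    stop("analyzer failed on ", encodeString(text, quote = "\""), ": ",
         conditionMessage(e), call. = FALSE)
  })
  if (!inherits(out, "token_seq")) {
    stop("analyzer did not return a token_seq for ",
         encodeString(text, quote = "\""), call. = FALSE)
  }
  out
}

#' Optional adapter for an external MeCab-compatible analyzer
#'
#' Shells out to a `mecab`-style command and maps its native POS tags onto
#' the coarse set. This adapter is entirely optional: nothing in the package
#' requires it, and all tests run on the fixture tokenizer. A user dictionary
#' (for example a medical-term dictionary) can be supplied via `user_dict`.
#'
#' @param command Path to the analyzer executable.
#' @param user_dict Optional path to a user dictionary passed via `-u`.
#' @param mapping Native-to-coarse tag mapping for [map_pos()].
#' @return A tokenizer adapter function, or an error if the command is not
#'   found.
#' @export
mecab_tokenizer <- function(command = "mecab", user_dict = NULL,
                            mapping = default_pos_mapping()) {
  if (!nzchar(Sys.which(command))) {
    stop("analyzer command not found: ", command, call. = FALSE)
  }
  args <- character()
  if (!is.null(user_dict)) args <- c("-u", user_dict)
  function(text) {
    if (!nzchar(text)) return(token_seq())
    lines <- suppressWarnings(
      system2(command, args = args, input = text, stdout = TRUE)
    )
    lines <- lines[nzchar(lines) & lines != "EOS"]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    surface <- vapply(parts, `[[`, character(1), 1L)
    native <- vapply(parts, function(p) {
      if (length(p) < 2L) return("")
      strsplit(p[[2L]], ",", fixed = TRUE)[[1L]][1L]
    }, character(1))
    token_seq(surface = surface, pos = map_pos(native, mapping),
              source_text = text, pos_detail = native)
  }
}
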
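# Anomalous-feature detection on translation candidates.
#
# A candidate label is anomalous when it looks sentence-like or unfinished
# rather than like a noun-phrase term: it contains a verb or ends in a
# non-noun word (F1), contains particles or adjectival verbs (F2), contains
# adjectives (F3), contains Japanese commas (F4), contains untranslated
# Latin-script words (F5), or is blank (F6). F1-F3 need morphological
# tokens; F4-F6 are computed from the string alone.

#' Anomalous feature tags
#'
#' @return Character vector of the six feature tags, in canonical order.
#' @export
anomaly_features <- function() {
  c("F1_VERB_OR_NONNOUN_END", "F2_PARTICLE_OR_ADJVERB", "F3_ADJECTIVE",
    "F4_JA_COMMA", "F5_UNTRANSLATED_LATIN", "F6_BLANK")
}

token_level_features <- function() anomaly_features()[1:3]

#' Japanese comma codepoints flagged by the comma feature
#'
#' The ideographic comma U+3001 and the fullwidth comma U+FF0C; both render
#' as Japanese-text commas and either one inside a term label is unusual
#' (unlike an ASCII comma in an English label).
#'
#' @return Character vector of single-character strings.
#' @export
ja_comma_chars <- function() c("、", "，")

#' Normalize a label for comparison
#'
#' Applies Unicode compatibility normalization (NFKC: halfwidth katakana to
#' fullwidth, fullwidth Latin/digits to ASCII, ideographic space to ASCII
#' space), strips leading/trailing whitespace and collapses internal
#' whitespace runs to one ASCII space. Idempotent. All voting and
#' harmonization equality tests run on normalized labels.
#'
#' Characters in `preserve` are shielded from NFKC; by default these are the
#' Japanese comma codepoints, because NFKC would fold the fullwidth comma
#' U+FF0C into an ASCII comma and erase the signal the comma anomaly feature
#' looks for.
#'
#' @param x Character vector of raw labels (NA treated as empty).
#' @param preserve Characters exempted from NFKC folding.
#' @return Character vector of normalized labels.
#' @examples
#' normalize_label("　不眠症 ")  # "不眠症"
#' @export
normalize_label <- function(x, preserve = ja_comma_chars()) {
  stopifnot(is.character(x))
  if (length(x) == 0L) return(character(0))
  x[is.na(x)] <- ""
  # shield preserved characters behind private-use placeholders during NFKC
  ph <- vapply(seq_along(preserve), function(i) intToUtf8(0xE000 + i - 1L),
               character(1))
  for (i in seq_along(preserve)) x <- gsub(preserve[i], ph[i], x, fixed = TRUE)
  x <- stringi::stri_trans_nfkc(x)
  for (i in seq_along(preserve)) x <- gsub(ph[i], preserve[i], x, fixed = TRUE)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Detect anomalous features on one candidate label
#'
#' String-level features (F4 comma, F5 Latin script, F6 blank) are always
#' computable; token-level features (F1-F3) require a token sequence. A
#' candidate exempt from morphological analysis is scored with
#' `tokens = NULL`, in which case only string-level features can appear in
#' the report. Calling with `tokens = NULL` while the candidate is declared
#' `analyzable` and any token-level feature is active is a contract error.
#'
#' @param label Normalized label string (see [normalize_label()]).
#' @param tokens A `token_seq` for the label, or NULL when the candidate is
#'   not morphologically analyzed.
#' @param active Subset of [anomaly_features()] currently in force; the
#'   report is restricted to it. Defaults to all six.
#' @param analyzable Declares whether this candidate was supposed to be
#'   analyzed; defaults to `!is.null(tokens)`.
#' @param term_id,source_tag Provenance carried into the report.
#' @param comma_chars Comma codepoints for the comma feature.
#' @return An object of class `feature_report` with fields `term_id`,
#'   `source_tag`, `features` (character subset of `active`), `analyzed`.
#' @export
detect_features <- function(label, tokens = NULL,
                            active = anomaly_features(),
                            analyzable = !is.null(tokens),
                            term_id = NA_character_,
                            source_tag = NA_character_,
                            comma_chars = ja_comma_chars()) {
  stopifnot(is.character(label), length(label) == 1L, !is.na(label))
  bad <- setdiff(active, anomaly_features())
  if (length(bad)) {
    stop("unknown feature tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  feats <- character(0)
  if (!nzchar(label)) {
    # a blank candidate carries no other feature
    feats <- "F6_BLANK"
    tokens <- NULL
  } else {
    if (is.null(tokens) && analyzable &&
        length(intersect(token_level_features(), active))) {
      stop("tokens missing for analyzable candidate ",
           encodeString(label, quote = "\""), call. = FALSE)
    }
    if (any(vapply(comma_chars, grepl, logical(1), x = label, fixed = TRUE))) {
      feats <- c(feats, "F4_JA_COMMA")
    }
    if (grepl("[A-Za-zＡ-Ｚａ-ｚ]", label)) {
      feats <- c(feats, "F5_UNTRANSLATED_LATIN")
    }
    if (!is.null(tokens)) {
      if (!inherits(tokens, "token_seq")) {
        stop("tokens must be a token_seq", call. = FALSE)
      }
      pos <- tokens$pos
      if (length(pos)) {
        if (any(pos == "VERB") ||
            !(pos[length(pos)] %in% c("NOUN", "SUFFIX"))) {
          feats <- c(feats, "F1_VERB_OR_NONNOUN_END")
        }
        if (any(pos %in% c("PARTICLE", "ADJECTIVAL_VERB"))) {
          feats <- c(feats, "F2_PARTICLE_OR_ADJVERB")
        }
        if (any(pos == "ADJECTIVE")) {
          feats <- c(feats, "F3_ADJECTIVE")
        }
      }
    }
  }
  feats <- intersect(anomaly_features(), feats)  # canonical order
  feats <- intersect(feats, active)
  structure(
    list(term_id = term_id, source_tag = source_tag, features = feats,
         analyzed = !is.null(tokens)),
    class = "feature_report"
  )
}

#' Is a candidate anomalous under the active feature set?
#'
#' Every active feature counts: a candidate is anomalous iff its report
#' contains at least one feature. Features are kept as separate labels so
#' the exclusion criteria can be changed by re-running with a different
#' `active` set.
#'
#' @param report A `feature_report` from [detect_features()].
#' @return TRUE iff the report carries at least one feature.
#' @export
is_anomalous <- function(report) {
  stopifnot(inherits(report, "feature_report"))
  length(report$features) > 0L
}

#' @export
print.feature_report <- function(x, ...) {
  cat("<feature_report",
      if (!is.na(x$term_id)) paste0(" ", x$term_id),
      if (!is.na(x$source_tag)) paste0("/", x$source_tag),
      ": ", sep = "")
  cat(if (length(x$features)) paste(x$features, collapse = ",") else "clean",
      if (!x$analyzed) " (not analyzed)", ">\n", sep = "")
  invisible(x)
}
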
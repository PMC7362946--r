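# Sub-classification of two competing candidate labels.
#
# When two candidates survive for one term, the disagreement is usually one
# of three kinds: the labels differ only by a near-meaningless trailing stop
# character (e.g. 症 "-pathy/syndrome"); the same translated words appear in
# a different order; or the labels genuinely diverge in meaning, which
# usually indicates a mistranslation on one side.

#' Strip trailing stop characters from a label
#'
#' Removes the trailing run of characters drawn from `stop_chars`.
#' Idempotent. A label consisting wholly of stop characters is returned
#' unchanged, so a non-empty input never becomes empty.
#'
#' @param label Character vector of normalized labels.
#' @param stop_chars Character vector of single stop characters
#'   (default `"症"`).
#' @return Character vector of stripped labels.
#' @examples
#' strip_stop_chars("不眠症")  # "不眠"
#' @export
strip_stop_chars <- function(label, stop_chars = "症") {
  stopifnot(is.character(label))
  stop_set <- unique(unlist(strsplit(stop_chars, "", fixed = TRUE)))
  vapply(label, function(s) {
    if (!nzchar(s)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    k <- n
    while (k >= 1L && chars[k] %in% stop_set) k <- k - 1L
    if (k == 0L) s else paste(chars[seq_len(k)], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Classify a pair of competing candidate labels
#'
#' `NEAR_IDENTICAL` when the labels agree after stop-character stripping;
#' otherwise `PERMUTED` when the multisets of token surfaces agree (same
#' translated words, different order); otherwise `DIVERGENT` (the residual
#' class — typically one side is a mistranslation; no semantic model is
#' attempted). Symmetric in its two arguments.
#'
#' @param a,b Normalized, non-empty labels.
#' @param tokenizer Tokenizer adapter used for the permutation test.
#' @param stop_chars Stop characters for [strip_stop_chars()].
#' @return An object of class `pair_verdict` with fields `group` (one of
#'   `NEAR_IDENTICAL`, `PERMUTED`, `DIVERGENT`) and `evidence` (list with
#'   `stripped_a`, `stripped_b`, `token_multiset_equal`).
#' @examples
#' classify_pair("不眠", "不眠症")
#' @export
classify_pair <- function(a, b, tokenizer = fixture_tokenizer(),
                          stop_chars = "症") {
  stopifnot(is.character(a), length(a) == 1L, nzchar(a),
            is.character(b), length(b) == 1L, nzchar(b))
  sa <- strip_stop_chars(a, stop_chars)
  sb <- strip_stop_chars(b, stop_chars)
  ta <- sort(tokenize(a, tokenizer)$surface)
  tb <- sort(tokenize(b, tokenizer)$surface)
  multiset_equal <- identical(ta, tb)
  group <- if (identical(sa, sb)) {
    "NEAR_IDENTICAL"
  } else if (multiset_equal) {
    "PERMUTED"
  } else {
    "DIVERGENT"
  }
  structure(
    list(group = group,
         evidence = list(stripped_a = sa, stripped_b = sb,
                         token_multiset_equal = multiset_equal)),
    class = "pair_verdict"
  )
}

#' @export
print.pair_verdict <- function(x, ...) {
  cat("<pair_verdict: ", x$group, " (", x$evidence$stripped_a, " vs ",
      x$evidence$stripped_b, ")>\n", sep = "")
  invisible(x)
}
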
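# Selecting one preferable translation per term.
#
# Decision list (default order):
#   1. All candidates blank -> BLANK.
#   2. Majority vote over non-blank normalized labels: a value with the
#      strictly largest multiplicity >= 2 wins (UNIQUE_MAJORITY); a 2-2 tie
#      yields TWO_CANDIDATES_MAJORITY.
#   3. Otherwise an exclusion process: candidates with any active anomalous
#      feature are excluded; 1 survivor -> UNIQUE_EXCLUSION, >= 2 survivors
#      -> MULTIPLE_EXCLUSION, 0 -> NONE_EXCLUSION. Candidates from exempt
#      sources (e.g. a dictionary whose entries are word-by-word
#      combinations that the analyzer would mis-segment) take part in the
#      vote but not in the exclusion stage.

#' Selection outcome taxonomy
#'
#' @return Character vector of the six outcome labels.
#' @export
selection_outcomes <- function() {
  c("UNIQUE_MAJORITY", "UNIQUE_EXCLUSION", "TWO_CANDIDATES_MAJORITY",
    "MULTIPLE_EXCLUSION", "NONE_EXCLUSION", "BLANK")
}

#' Majority vote over a candidate set
#'
#' Blanks are excluded from voting (a blank is not a translation). A value
#' whose multiplicity is at least two and strictly larger than every other
#' value's wins outright; exactly two distinct values tied at multiplicity
#' two (and none higher) form a 2-2 tie; anything else — all distinct, or
#' three-plus values tied at the top — is no majority.
#'
#' @param candidates A [candidate_set] (labels are normalized internally).
#' @return A list with `kind` in `c("UNIQUE", "TIE_2_2", "NONE")` and
#'   `values`: the winning value, the two tied values in candidate-source
#'   order, or `character(0)`.
#' @export
majority_vote <- function(candidates) {
  stopifnot(inherits(candidates, "candidate_set"))
  labs <- normalize_label(candidates$labels)
  labs <- labs[nzchar(labs)]
  if (length(labs) == 0L) return(list(kind = "NONE", values = character(0)))
  first_seen <- labs[!duplicated(labs)]
  mult <- table(factor(labs, levels = first_seen))
  top <- max(mult)
  winners <- first_seen[mult == top]  # candidate-source order
  if (top >= 2L && length(winners) == 1L) {
    list(kind = "UNIQUE", values = winners)
  } else if (top == 2L && length(winners) == 2L) {
    list(kind = "TIE_2_2", values = winners)
  } else {
    list(kind = "NONE", values = character(0))
  }
}

#' Exclusion ranking of candidates by anomalous features
#'
#' Survivors are the non-blank, non-exempt candidates whose feature report
#' is clean, deduplicated after normalization, in source order. Exempt
#' sources carry no morphological analysis, so they can neither be excluded
#' nor survive.
#'
#' @param candidates A [candidate_set].
#' @param reports List of `feature_report`s; every non-exempt candidate must
#'   have one (matched by source tag).
#' @param exempt_sources Source tags exempt from the exclusion stage.
#' @return Character vector of surviving normalized labels (possibly empty).
#' @export
exclusion_rank <- function(candidates, reports, exempt_sources = character()) {
  stopifnot(inherits(candidates, "candidate_set"))
  report_tags <- vapply(reports, `[[`, character(1), "source_tag")
  labs <- normalize_label(candidates$labels)
  survivors <- character(0)
  for (i in seq_along(candidates$sources)) {
    src <- candidates$sources[i]
    if (src %in% exempt_sources) next
    if (!nzchar(labs[i])) next
    j <- match(src, report_tags)
    if (is.na(j)) {
      stop("missing feature report for non-exempt candidate source '", src,
           "' of term ", candidates$term_id, call. = FALSE)
    }
    if (!is_anomalous(reports[[j]])) survivors <- c(survivors, labs[i])
  }
  unique(survivors)
}

#' Select the preferable translation for one term
#'
#' Runs the full decision list over a candidate set: blank check, majority
#' vote, then the exclusion process (order configurable through
#' `config$stage_order`; `"exclusion_first"` drops anomalous non-exempt
#' candidates before voting). Token-level features are obtained through the
#' tokenizer adapter for every non-exempt, non-blank candidate.
#'
#' @param candidates A [candidate_set].
#' @param tokenizer Tokenizer adapter (e.g. [fixture_tokenizer()]).
#' @param config A [run_config()] naming exempt sources, active features and
#'   stage order.
#' @param .exclusion Exclusion-stage function, overridable for testing.
#' @return An object of class `selection_result` with fields `term_id`,
#'   `outcome` (one of [selection_outcomes()]), `chosen` (normalized labels:
#'   1 for UNIQUE_*, 2 for TWO_CANDIDATES_MAJORITY, >= 2 for
#'   MULTIPLE_EXCLUSION, 0 otherwise) and `reports` (per-candidate feature
#'   reports).
#' @export
select_label <- function(candidates, tokenizer = fixture_tokenizer(),
                         config = run_config(),
                         .exclusion = exclusion_rank) {
  stopifnot(inherits(candidates, "candidate_set"))
  exempt <- config$exempt_sources
  active <- config$active_features
  labs <- normalize_label(candidates$labels)

  reports <- lapply(seq_along(candidates$sources), function(i) {
    src <- candidates$sources[i]
    lab <- labs[i]
    if (src %in% exempt || !nzchar(lab)) {
      detect_features(lab, tokens = NULL, active = active, analyzable = FALSE,
                      term_id = candidates$term_id, source_tag = src)
    } else {
      detect_features(lab, tokens = tokenize(lab, tokenizer), active = active,
                      term_id = candidates$term_id, source_tag = src)
    }
  })

  result <- function(outcome, chosen) {
    structure(list(term_id = candidates$term_id, outcome = outcome,
                   chosen = chosen, reports = reports),
              class = "selection_result")
  }

  if (all(!nzchar(labs))) return(result("BLANK", character(0)))

  voting_set <- candidates
  if (identical(config$stage_order, "exclusion_first")) {
    drop <- vapply(seq_along(candidates$sources), function(i) {
      src <- candidates$sources[i]
      !(src %in% exempt) && nzchar(labs[i]) && is_anomalous(reports[[i]])
    }, logical(1))
    kept <- candidates$labels
    kept[drop] <- ""
    voting_set <- candidate_set(candidates$term_id, kept,
                                sources = candidates$sources)
  }

  vote <- majority_vote(voting_set)
  if (vote$kind == "UNIQUE") return(result("UNIQUE_MAJORITY", vote$values))
  if (vote$kind == "TIE_2_2") {
    return(result("TWO_CANDIDATES_MAJORITY", vote$values))
  }

  survivors <- .exclusion(candidates, reports, exempt_sources = exempt)
  if (length(survivors) == 1L) {
    result("UNIQUE_EXCLUSION", survivors)
  } else if (length(survivors) >= 2L) {
    result("MULTIPLE_EXCLUSION", survivors)
  } else {
    result("NONE_EXCLUSION", character(0))
  }
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result ", x$term_id, ": ", x$outcome, sep = "")
  if (length(x$chosen)) cat(" [", paste(x$chosen, collapse = " | "), "]",
                            sep = "")
  cat(">\n")
  invisible(x)
}

#' Select labels for a whole candidate table
#'
#' @param sets List of [candidate_set] objects.
#' @inheritParams select_label
#' @return List of `selection_result`s, in input order.
#' @export
select_labels <- function(sets, tokenizer = fixture_tokenizer(),
                          config = run_config()) {
  lapply(sets, select_label, tokenizer = tokenizer, config = config)
}

#' Summarize selection outcomes
#'
#' Counts per outcome plus the rollup `UNIQUE` (= UNIQUE_MAJORITY +
#' UNIQUE_EXCLUSION, the terms that end up with a single preferable label).
#'
#' @param results List of `selection_result`s.
#' @return An object of class `label_summary`: named integer vector with
#'   `ALL_TERMS`, `UNIQUE`, and one entry per outcome. Outcome counts sum to
#'   `ALL_TERMS`.
#' @export
summarize_labels <- function(results) {
  outcomes <- vapply(results, `[[`, character(1), "outcome")
  counts <- table(factor(outcomes, levels = selection_outcomes()))
  out <- c(
    ALL_TERMS = length(results),
    UNIQUE = unname(counts[["UNIQUE_MAJORITY"]] +
                      counts[["UNIQUE_EXCLUSION"]]),
    stats::setNames(as.integer(counts), names(counts))
  )
  structure(out, class = "label_summary")
}

#' @export
print.label_summary <- function(x, ...) {
  rows <- c(
    "All terms" = "ALL_TERMS",
    "A unique translation" = "UNIQUE",
    "  determined by a majority" = "UNIQUE_MAJORITY",
    "  determined by an exclusion process" = "UNIQUE_EXCLUSION",
    "Two appropriate candidates (majority)" = "TWO_CANDIDATES_MAJORITY",
    "Multiple appropriate candidates (exclusion)" = "MULTIPLE_EXCLUSION",
    "No appropriate candidates (exclusion)" = "NONE_EXCLUSION",
    "BLANK" = "BLANK"
  )
  width <- max(nchar(names(rows)))
  for (i in seq_along(rows)) {
    cat(formatC(names(rows)[i], width = -width), " ",
        format(unclass(x)[[rows[i]]], big.mark = ","), "\n", sep = "")
  }
  invisible(x)
}
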
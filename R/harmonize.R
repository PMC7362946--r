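# Harmonization of translations between two ontologies.
#
# Concept-equivalence pairs (side "a" vs side "b"; in the motivating use
# case HPO vs the Mammalian Phenotype ontology) are compared by exact
# character-string equality of their English and translated labels after
# normalization, giving a 2x2 grid plus a missing-translation class, each
# with a recommended action. The precedence side ("a" by default) is the
# translation that wins when only the English labels agree — unless a
# species-variant lexicon explains the difference (terms such as male/female
# are legitimately rendered 男性/女性 for humans but オス/メス for other
# mammals), in which case both renderings are kept.

#' Harmonization categories
#'
#' @return Character vector of the five category labels.
#' @export
harmonization_categories <- function() {
  c("BOTH_SAME", "EN_SAME_ONLY", "JA_SAME_ONLY", "BOTH_DIFFERENT",
    "NO_JA_CANDIDATE")
}

#' Construct a concept-equivalence pair
#'
#' @param id_a,id_b Concept identifiers on each side.
#' @param label_en_a,label_en_b English labels.
#' @param label_ja_a,label_ja_b Translated labels; `NA` marks a translation
#'   that does not exist yet (distinct from a label that normalizes to the
#'   empty string).
#' @return An object of class `concept_pair`.
#' @export
concept_pair <- function(id_a, id_b, label_en_a, label_en_b,
                         label_ja_a = NA_character_,
                         label_ja_b = NA_character_) {
  structure(
    list(id_a = as.character(id_a), id_b = as.character(id_b),
         label_en_a = as.character(label_en_a),
         label_en_b = as.character(label_en_b),
         label_ja_a = as.character(label_ja_a),
         label_ja_b = as.character(label_ja_b),
         ja_absent_a = is.na(label_ja_a),
         ja_absent_b = is.na(label_ja_b)),
    class = "concept_pair"
  )
}

#' Classify a concept pair on the same/different grid
#'
#' If a translated label is absent on either side the pair is
#' `NO_JA_CANDIDATE`; otherwise English labels and translated labels are
#' compared for exact equality after [normalize_label()] and mapped to the
#' 2x2 grid. The four grid categories are mutually exclusive and exhaustive
#' over pairs with both translations present.
#'
#' @param pair A [concept_pair()].
#' @return One of [harmonization_categories()].
#' @export
classify_concept_pair <- function(pair) {
  stopifnot(inherits(pair, "concept_pair"))
  if (pair$ja_absent_a || pair$ja_absent_b) return("NO_JA_CANDIDATE")
  en_same <- identical(normalize_label(pair$label_en_a),
                       normalize_label(pair$label_en_b))
  ja_same <- identical(normalize_label(pair$label_ja_a),
                       normalize_label(pair$label_ja_b))
  if (en_same && ja_same) "BOTH_SAME"
  else if (en_same) "EN_SAME_ONLY"
  else if (ja_same) "JA_SAME_ONLY"
  else "BOTH_DIFFERENT"
}

#' Construct a species-variant lexicon
#'
#' Pairs of renderings of the same word for humans vs non-human mammals
#' (e.g. 男性/オス "male", 女性/メス "female").
#'
#' @param human_form,animal_form Equal-length character vectors of non-empty
#'   forms; `human_form` entries must be unique.
#' @return An object of class `species_lexicon`.
#' @export
species_lexicon <- function(human_form, animal_form) {
  human_form <- as.character(human_form)
  animal_form <- as.character(animal_form)
  stopifnot(length(human_form) == length(animal_form))
  if (any(!nzchar(human_form)) || any(!nzchar(animal_form))) {
    stop("lexicon forms must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(human_form)) {
    stop("duplicate human_form entries", call. = FALSE)
  }
  structure(
    data.frame(human_form = human_form, animal_form = animal_form,
               stringsAsFactors = FALSE),
    class = c("species_lexicon", "data.frame")
  )
}

#' The default species-variant lexicon
#'
#' @return A [species_lexicon()] with the male/female pairs 男性/オス and
#'   女性/メス.
#' @export
default_species_lexicon <- function() {
  species_lexicon(human_form = c("男性", "女性"),
                  animal_form = c("オス", "メス"))
}

#' Read a species-variant lexicon from TSV
#'
#' @param path TSV with columns `human_form`, `animal_form`.
#' @return A [species_lexicon()].
#' @export
read_species_lexicon <- function(path) {
  df <- tsv_read(path)
  missing <- setdiff(c("human_form", "animal_form"), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  species_lexicon(df$human_form, df$animal_form)
}

substitute_forms <- function(x, from, to) {
  ord <- order(nchar(from), decreasing = TRUE)  # longest form first
  for (i in ord) x <- gsub(from[i], to[i], x, fixed = TRUE)
  x
}

#' Does a species-variant substitution explain a label difference?
#'
#' Both labels are rewritten to a canonical form by replacing every
#' occurrence of each lexicon form (longest form first): TRUE iff the two
#' labels agree after mapping animal forms to their human forms, or after
#' mapping human forms to their animal forms. This contains the directed
#' reading (animal forms in `ja_b` rewritten to human forms yield `ja_a`,
#' or vice versa) and is symmetric in the two labels regardless of which
#' side carries the animal rendering.
#'
#' @param ja_a,ja_b Normalized, non-empty translated labels.
#' @param lexicon A [species_lexicon()].
#' @return Logical scalar.
#' @examples
#' species_variant_explains("女性", "メス", default_species_lexicon())
#' @export
species_variant_explains <- function(ja_a, ja_b,
                                     lexicon = default_species_lexicon()) {
  stopifnot(inherits(lexicon, "species_lexicon"),
            is.character(ja_a), nzchar(ja_a),
            is.character(ja_b), nzchar(ja_b))
  to_human <- function(x) substitute_forms(x, lexicon$animal_form,
                                           lexicon$human_form)
  to_animal <- function(x) substitute_forms(x, lexicon$human_form,
                                            lexicon$animal_form)
  identical(to_human(ja_a), to_human(ja_b)) ||
    identical(to_animal(ja_a), to_animal(ja_b))
}

#' Recommend a harmonization action for a classified pair
#'
#' `BOTH_SAME` pairs need nothing (`KEEP`). When only the English labels
#' agree the precedence side's translation wins (`UNIFY_TO_A`) unless the
#' species lexicon explains the difference, in which case both renderings
#' are legitimate (`SPECIES_VARIANT_KEEP`). When only the translations agree
#' nothing is changed (`NO_CHANGE`; whether the concepts are close enough is
#' surfaced as a curator warning, not computed). `BOTH_DIFFERENT` pairs go
#' to `MANUAL_CURATION`; missing translations `AWAIT_TRANSLATION`.
#'
#' @param category One of [harmonization_categories()].
#' @param pair The [concept_pair()] (needed for the species check).
#' @param lexicon A [species_lexicon()] or NULL to disable the species
#'   exception.
#' @return A single action string.
#' @export
recommend_action <- function(category, pair = NULL,
                             lexicon = default_species_lexicon()) {
  category <- match.arg(category, harmonization_categories())
  switch(category,
    BOTH_SAME = "KEEP",
    EN_SAME_ONLY = {
      explained <- !is.null(lexicon) && !is.null(pair) &&
        species_variant_explains(normalize_label(pair$label_ja_a),
                                 normalize_label(pair$label_ja_b), lexicon)
      if (explained) "SPECIES_VARIANT_KEEP" else "UNIFY_TO_A"
    },
    JA_SAME_ONLY = "NO_CHANGE",
    BOTH_DIFFERENT = "MANUAL_CURATION",
    NO_JA_CANDIDATE = "AWAIT_TRANSLATION"
  )
}

#' Harmonize a table of concept pairs
#'
#' Classifies every pair and attaches the recommended action. The
#' `precedence` argument names which side's translation wins for
#' `EN_SAME_ONLY` pairs; with `precedence = "b"` the sides are swapped
#' before classification and the unify action still reads `UNIFY_TO_A`
#' relative to the swapped orientation (reported as `UNIFY_TO_B` in the
#' original orientation).
#'
#' @param pairs A data.frame as returned by [read_equivalence_map()].
#' @param lexicon A [species_lexicon()] or NULL.
#' @param precedence `"a"` or `"b"`.
#' @return A data.frame with the input columns plus `category`, `action`
#'   and `warning` (flag for JA_SAME_ONLY pairs: concept similarity is
#'   assumed, not checked).
#' @export
harmonize_pairs <- function(pairs, lexicon = default_species_lexicon(),
                            precedence = c("a", "b")) {
  precedence <- match.arg(precedence)
  stopifnot(is.data.frame(pairs))
  n <- nrow(pairs)
  category <- character(n)
  action <- character(n)
  warning_flag <- character(n)
  for (i in seq_len(n)) {
    row <- pairs[i, ]
    cp <- concept_pair(
      row$id_a, row$id_b, row$label_en_a, row$label_en_b,
      label_ja_a = if (isTRUE(row$ja_absent_a)) NA_character_ else row$label_ja_a,
      label_ja_b = if (isTRUE(row$ja_absent_b)) NA_character_ else row$label_ja_b
    )
    if (precedence == "b") {
      cp <- concept_pair(row$id_b, row$id_a, row$label_en_b, row$label_en_a,
                         label_ja_a = if (isTRUE(row$ja_absent_b)) NA_character_
                                      else row$label_ja_b,
                         label_ja_b = if (isTRUE(row$ja_absent_a)) NA_character_
                                      else row$label_ja_a)
    }
    category[i] <- classify_concept_pair(cp)
    act <- recommend_action(category[i], cp, lexicon)
    if (precedence == "b" && act == "UNIFY_TO_A") act <- "UNIFY_TO_B"
    action[i] <- act
    warning_flag[i] <- if (category[i] == "JA_SAME_ONLY") {
      "concept_similarity_not_checked"
    } else ""
  }
  out <- pairs
  out$category <- category
  out$action <- action
  out$warning <- warning_flag
  out
}

#' Summarize harmonization categories
#'
#' @param results Data.frame from [harmonize_pairs()] (needs a `category`
#'   column).
#' @return An object of class `harmonization_summary`: named integer vector
#'   with `ALL_PAIRS`, `WITH_BOTH_JA` (pairs entering the 2x2 grid) and one
#'   entry per category. The four grid counts sum to `WITH_BOTH_JA`.
#' @export
summarize_harmonization <- function(results) {
  cats <- if (is.data.frame(results)) results$category
          else vapply(results, `[[`, character(1), "category")
  counts <- table(factor(cats, levels = harmonization_categories()))
  out <- c(
    ALL_PAIRS = length(cats),
    WITH_BOTH_JA = length(cats) - unname(counts[["NO_JA_CANDIDATE"]]),
    stats::setNames(as.integer(counts), names(counts))
  )
  structure(out, class = "harmonization_summary")
}

#' @export
print.harmonization_summary <- function(x, ...) {
  rows <- c(
    "All concept pairs" = "ALL_PAIRS",
    "  with translations on both sides" = "WITH_BOTH_JA",
    "Both labels the same in both languages" = "BOTH_SAME",
    "Only the English labels the same" = "EN_SAME_ONLY",
    "Only the translated labels the same" = "JA_SAME_ONLY",
    "Both labels different in both languages" = "BOTH_DIFFERENT",
    "Translation does not exist yet" = "NO_JA_CANDIDATE"
  )
  width <- max(nchar(names(rows)))
  for (i in seq_along(rows)) {
    cat(formatC(names(rows)[i], width = -width), " ",
        format(unclass(x)[[rows[i]]], big.mark = ","), "\n", sep = "")
  }
  invisible(x)
}
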
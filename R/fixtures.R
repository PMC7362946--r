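# Seeded synthetic fixtures with planted ground truth.
#
# Labels are assembled from a small pool of real-looking anatomical nouns
# plus planted verbs/particles/adjectives, so the gold token annotation of
# every generated label is correct by construction and no morphological
# analyzer is needed anywhere in the test surface. The noun pool contains no
# prefix relations between entries, which guarantees that two labels built
# from different leading nouns are distinct strings.

fixture_nouns <- function() {
  c("心臓", "肝臓", "腎臓", "脾臓", "肺胞", "脳幹", "眼球",
    "網膜", "角膜", "脊椎", "大腿骨", "尺骨", "橈骨", "頭蓋",
    "皮膚", "血管", "関節", "筋肉", "甲状腺", "膵臓")
}

fixture_latin_words <- function() c("stromal", "distal", "proximal", "focal")

fixture_organs_en <- function() {
  c("heart", "liver", "kidney", "spleen", "lung", "brainstem", "eye",
    "retina", "cornea", "spine", "femur", "ulna", "radius", "skull",
    "skin", "vessel", "joint", "muscle", "thyroid", "pancreas")
}

uniform_mix <- function(levels) {
  stats::setNames(rep(1 / length(levels), length(levels)), levels)
}

check_mix <- function(mix, levels, what) {
  if (is.null(names(mix)) || !setequal(names(mix), levels)) {
    stop(what, " must be a named probability vector over: ",
         paste(levels, collapse = ", "), call. = FALSE)
  }
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-9) {
    stop(what, " must be non-negative and sum to 1", call. = FALSE)
  }
  mix[levels]
}

#' Specify a synthetic fixture
#'
#' @param n_terms Number of terms (or concept pairs) to generate.
#' @param outcome_mix Named probability vector over [selection_outcomes()]
#'   (default uniform): the planted selection outcomes.
#' @param anomaly_mix Named probability vector over the five non-blank
#'   anomaly features (default uniform): which feature a planted anomalous
#'   candidate exhibits.
#' @param pair_mix Named probability vector over
#'   [harmonization_categories()] (default uniform).
#' @param species_rate Probability that a planted `EN_SAME_ONLY` pair is a
#'   species-variant case (default 0.5, so both branches of the species
#'   exception are well represented).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_terms = 500L,
                         outcome_mix = uniform_mix(selection_outcomes()),
                         anomaly_mix = uniform_mix(anomaly_features()[1:5]),
                         pair_mix = uniform_mix(harmonization_categories()),
                         species_rate = 0.5,
                         seed = 1L) {
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L) stop("n_terms must be >= 1",
                                           call. = FALSE)
  structure(
    list(
      n_terms = n_terms,
      outcome_mix = check_mix(outcome_mix, selection_outcomes(),
                              "outcome_mix"),
      anomaly_mix = check_mix(anomaly_mix, anomaly_features()[1:5],
                              "anomaly_mix"),
      pair_mix = check_mix(pair_mix, harmonization_categories(), "pair_mix"),
      species_rate = species_rate,
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate a candidate table with planted selection outcomes
#'
#' For each term an outcome is drawn from `spec$outcome_mix` and a candidate
#' set is constructed that provably realizes it: majority winners get the
#' required multiplicity, exclusion outcomes get exactly the required number
#' of clean non-exempt candidates, anomalous candidates carry one planted
#' feature drawn from `spec$anomaly_mix`, and all non-planted labels within
#' a term are pairwise distinct. Gold token annotations cover every
#' generated non-blank label.
#'
#' @param spec A [fixture_spec()].
#' @param sources Source tags (default the motivating four-source setup).
#' @param exempt_sources Sources exempt from the exclusion stage.
#' @return A list with `candidates` (list of [candidate_set]), `gold`
#'   (named list of `token_seq`, usable with [fixture_tokenizer()]) and
#'   `truth` (data.frame `term_id`, `outcome`, `chosen` with labels joined
#'   by `"|"`).
#' @export
generate_candidates <- function(spec,
                                sources = c("LSD", "MP", "EXPERT", "MT"),
                                exempt_sources = "LSD") {
  stopifnot(inherits(spec, "fixture_spec"))
  m <- length(sources)
  non_exempt <- setdiff(sources, exempt_sources)
  if (!all(exempt_sources %in% sources)) {
    stop("exempt_sources must be a subset of sources", call. = FALSE)
  }
  if (spec$outcome_mix[["TWO_CANDIDATES_MAJORITY"]] > 0 && m < 4L) {
    stop("TWO_CANDIDATES_MAJORITY requires at least 4 sources", call. = FALSE)
  }
  if (spec$outcome_mix[["MULTIPLE_EXCLUSION"]] > 0 && length(non_exempt) < 2L) {
    stop("MULTIPLE_EXCLUSION requires at least 2 non-exempt sources",
         call. = FALSE)
  }
  if (length(non_exempt) < 1L) {
    stop("at least one non-exempt source is required", call. = FALSE)
  }

  gold <- new.env(parent = emptyenv())
  remember <- function(label, surface, pos) {
    if (is.null(gold[[label]])) {
      gold[[label]] <- token_seq(surface, pos, source_text = label)
    }
    label
  }

  with_seed(spec$seed, {
    outcomes <- sample(selection_outcomes(), spec$n_terms, replace = TRUE,
                       prob = spec$outcome_mix)
    sets <- vector("list", spec$n_terms)
    chosen_truth <- character(spec$n_terms)

    for (i in seq_len(spec$n_terms)) {
      nouns <- sample(fixture_nouns(), 8L)
      slot <- 0L
      next_slot <- function() {
        slot <<- slot + 1L
        c(nouns[2L * slot - 1L], nouns[2L * slot])
      }
      clean_label <- function() {
        p <- next_slot()
        if (stats::runif(1) < 0.3) {
          remember(paste0(p[1], p[2], "症"),
                   c(p[1], p[2], "症"), c("NOUN", "NOUN", "SUFFIX"))
        } else {
          remember(paste0(p[1], p[2]), p, c("NOUN", "NOUN"))
        }
      }
      anomalous_label <- function() {
        p <- next_slot()
        feat <- sample(names(spec$anomaly_mix), 1L, prob = spec$anomaly_mix)
        switch(feat,
          F1_VERB_OR_NONNOUN_END = remember(
            paste0(p[1], p[2], "湾曲する"),
            c(p[1], p[2], "湾曲する"), c("NOUN", "NOUN", "VERB")),
          F2_PARTICLE_OR_ADJVERB = remember(
            paste0(p[1], "の", p[2]),
            c(p[1], "の", p[2]), c("NOUN", "PARTICLE", "NOUN")),
          F3_ADJECTIVE = remember(
            paste0("幅広い", p[1], p[2]),
            c("幅広い", p[1], p[2]), c("ADJECTIVE", "NOUN", "NOUN")),
          F4_JA_COMMA = remember(
            paste0(p[1], "、", p[2]),
            c(p[1], "、", p[2]), c("NOUN", "SYMBOL", "NOUN")),
          F5_UNTRANSLATED_LATIN = {
            latin <- sample(fixture_latin_words(), 1L)
            remember(paste0(p[1], latin, p[2]),
                     c(p[1], latin, p[2]), c("NOUN", "NOUN", "NOUN"))
          }
        )
      }
      filler_label <- function() {
        kind <- sample(c("clean", "anomalous", "blank"), 1L,
                       prob = c(0.5, 0.3, 0.2))
        switch(kind, clean = clean_label(),
               anomalous = anomalous_label(), blank = "")
      }

      labels <- rep("", m)
      outcome <- outcomes[i]
      ne_idx <- which(sources %in% non_exempt)
      ex_idx <- which(sources %in% exempt_sources)

      if (outcome == "BLANK") {
        chosen <- character(0)
      } else if (outcome == "UNIQUE_MAJORITY") {
        mult <- sample(2:m, 1L, prob = rev(seq_len(m - 1L)))
        v <- clean_label()
        pos <- sample(m, mult)
        labels[pos] <- v
        for (j in setdiff(seq_len(m), pos)) labels[j] <- filler_label()
        chosen <- v
      } else if (outcome == "TWO_CANDIDATES_MAJORITY") {
        v <- clean_label()
        w <- clean_label()
        perm <- sample(m, 4L)
        labels[perm[1:2]] <- v
        labels[perm[3:4]] <- w
        chosen <- if (min(perm[1:2]) < min(perm[3:4])) c(v, w) else c(w, v)
      } else if (outcome == "UNIQUE_EXCLUSION") {
        keep <- sample(ne_idx, 1L)
        labels[keep] <- clean_label()
        for (j in setdiff(ne_idx, keep)) labels[j] <- anomalous_label()
        for (j in ex_idx) labels[j] <- clean_label()
        chosen <- labels[keep]
      } else if (outcome == "MULTIPLE_EXCLUSION") {
        k <- sample(2:length(ne_idx), 1L)
        keep <- sort(sample(ne_idx, k))
        for (j in keep) labels[j] <- clean_label()
        for (j in setdiff(ne_idx, keep)) labels[j] <- anomalous_label()
        for (j in ex_idx) labels[j] <- clean_label()
        chosen <- labels[keep]
      } else {  # NONE_EXCLUSION
        for (j in ne_idx) labels[j] <- anomalous_label()
        for (j in ex_idx) labels[j] <- clean_label()
        chosen <- character(0)
      }

      sets[[i]] <- candidate_set(sprintf("SYN:%07d", i), labels,
                                 sources = sources)
      chosen_truth[i] <- paste(chosen, collapse = "|")
    }

    list(
      candidates = sets,
      gold = as.list(gold),
      truth = data.frame(
        term_id = vapply(sets, `[[`, character(1), "term_id"),
        outcome = outcomes,
        chosen = chosen_truth,
        stringsAsFactors = FALSE
      )
    )
  })
}

#' Generate a concept-pair table with planted harmonization categories
#'
#' For each pair a category is drawn from `spec$pair_mix` and English and
#' translated labels are constructed to realize it. Planted `EN_SAME_ONLY`
#' pairs are species-variant cases (built by substituting the default
#' species lexicon's forms) with probability `spec$species_rate`.
#'
#' @param spec A [fixture_spec()]; `spec$n_terms` is the number of pairs.
#' @return A list with `pairs` (data.frame in the shape of
#'   [read_equivalence_map()] output) and `truth` (data.frame `category`,
#'   `species_case`).
#' @export
generate_pairs <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  lex <- default_species_lexicon()
  with_seed(spec$seed + 1L, {
    n <- spec$n_terms
    cats <- sample(harmonization_categories(), n, replace = TRUE,
                   prob = spec$pair_mix)
    species_case <- logical(n)
    en_a <- en_b <- ja_a <- ja_b <- character(n)
    absent_a <- absent_b <- logical(n)

    for (i in seq_len(n)) {
      nouns <- sample(fixture_nouns(), 4L)
      words <- sample(fixture_organs_en(), 2L)
      en_same_lab <- paste("Abnormal", words[1], "morphology")
      en_diff_lab <- paste("Abnormal", words[2], "morphology")
      j1 <- paste0(nouns[1], nouns[2])
      j2 <- paste0(nouns[3], nouns[4])
      cat_i <- cats[i]

      if (cat_i == "BOTH_SAME") {
        en_a[i] <- en_b[i] <- en_same_lab
        ja_a[i] <- ja_b[i] <- j1
      } else if (cat_i == "EN_SAME_ONLY") {
        en_a[i] <- en_b[i] <- en_same_lab
        if (stats::runif(1) < spec$species_rate) {
          row <- lex[sample(nrow(lex), 1L), ]
          ja_a[i] <- paste0(row$human_form, nouns[1])
          ja_b[i] <- paste0(row$animal_form, nouns[1])
          species_case[i] <- TRUE
        } else {
          ja_a[i] <- j1
          ja_b[i] <- j2
        }
      } else if (cat_i == "JA_SAME_ONLY") {
        en_a[i] <- en_same_lab
        en_b[i] <- en_diff_lab
        ja_a[i] <- ja_b[i] <- j1
      } else if (cat_i == "BOTH_DIFFERENT") {
        en_a[i] <- en_same_lab
        en_b[i] <- en_diff_lab
        ja_a[i] <- j1
        ja_b[i] <- j2
      } else {  # NO_JA_CANDIDATE
        en_a[i] <- en_same_lab
        en_b[i] <- if (stats::runif(1) < 0.5) en_same_lab else en_diff_lab
        side <- sample(c("a", "b", "both"), 1L)
        if (side %in% c("a", "both")) absent_a[i] <- TRUE else ja_a[i] <- j1
        if (side %in% c("b", "both")) absent_b[i] <- TRUE else ja_b[i] <- j1
      }
    }

    pairs <- data.frame(
      id_a = sprintf("ONTA:%06d", seq_len(n)),
      id_b = sprintf("ONTB:%06d", seq_len(n)),
      label_en_a = en_a, label_en_b = en_b,
      label_ja_a = ja_a, label_ja_b = ja_b,
      ja_absent_a = absent_a, ja_absent_b = absent_b,
      stringsAsFactors = FALSE
    )
    list(pairs = pairs,
         truth = data.frame(category = cats, species_case = species_case,
                            stringsAsFactors = FALSE))
  })
}
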
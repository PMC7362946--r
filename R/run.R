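# Workflow runners: each reads its inputs, executes one pipeline stage and
# writes per-record plus summary reports. These are the functions the
# command-line wrapper (inst/cli/ontolabel.R) dispatches to.

results_to_records <- function(results, sources) {
  n <- length(results)
  rec <- data.frame(
    term_id = vapply(results, `[[`, character(1), "term_id"),
    outcome = vapply(results, `[[`, character(1), "outcome"),
    chosen = vapply(results, function(r) paste(r$chosen, collapse = "|"),
                    character(1)),
    stringsAsFactors = FALSE
  )
  for (src in sources) {
    rec[[paste0("features_", src)]] <- vapply(results, function(r) {
      tags <- vapply(r$reports, `[[`, character(1), "source_tag")
      j <- match(src, tags)
      if (is.na(j)) "" else paste(r$reports[[j]]$features, collapse = "+")
    }, character(1))
  }
  rec
}

summary_to_records <- function(s) {
  data.frame(key = names(unclass(s)),
             n = as.integer(unclass(s)),
             stringsAsFactors = FALSE)
}

#' Write gold token annotations to TSV
#'
#' One row per label; tokens serialized as space-separated `surface/POS`
#' items.
#'
#' @param gold Named list of `token_seq` objects.
#' @param path Output TSV path.
#' @export
write_gold_tokens <- function(gold, path) {
  labels <- names(gold)
  if (is.null(labels)) labels <- character(0)
  toks <- vapply(gold, function(ts) {
    paste(paste0(ts$surface, "/", ts$pos), collapse = " ")
  }, character(1))
  tsv_write(data.frame(label = labels, tokens = unname(toks),
                       stringsAsFactors = FALSE), path)
}

#' Read gold token annotations from TSV
#'
#' @param path TSV written by [write_gold_tokens()].
#' @return Named list of `token_seq` objects, usable with
#'   [fixture_tokenizer()].
#' @export
read_gold_tokens <- function(path) {
  df <- tsv_read(path)
  missing <- setdiff(c("label", "tokens"), names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    items <- strsplit(df$tokens[i], " ", fixed = TRUE)[[1L]]
    parts <- regmatches(items, regexpr("/[A-Z_]+$", items))
    surface <- sub("/[A-Z_]+$", "", items)
    pos <- sub("^/", "", parts)
    token_seq(surface, pos, source_text = df$label[i])
  })
  stats::setNames(out, df$label)
}

#' Run the label-selection workflow
#'
#' Reads a candidate table, selects one outcome per term and writes the
#' per-term report plus a summary (TSV, and JSON next to it).
#'
#' @param config A [run_config()].
#' @param candidates_path Input candidate TSV (`term_id` + source columns).
#' @param out_path Per-term report TSV.
#' @param summary_path Summary TSV (default `<out_path>.summary.tsv`); a
#'   `.json` twin is written as well.
#' @param gold_path Optional gold-token TSV; when given, the fixture
#'   tokenizer is built from it, otherwise a pure-fallback tokenizer is
#'   used.
#' @param tokenizer Explicit tokenizer adapter (overrides `gold_path`).
#' @return Invisibly, the list of `selection_result`s.
#' @export
run_select <- function(config, candidates_path, out_path,
                       summary_path = NULL, gold_path = NULL,
                       tokenizer = NULL) {
  sets <- read_candidate_table(candidates_path, sources = config$sources)
  if (is.null(tokenizer)) {
    gold <- if (is.null(gold_path)) list() else read_gold_tokens(gold_path)
    tokenizer <- fixture_tokenizer(gold)
  }
  results <- select_labels(sets, tokenizer = tokenizer, config = config)
  write_report(results_to_records(results, config$sources), out_path, "tsv")
  s <- summarize_labels(results)
  if (is.null(summary_path)) {
    summary_path <- paste0(out_path, ".summary.tsv")
  }
  write_report(summary_to_records(s), summary_path, "tsv")
  write_report(summary_to_records(s), sub("\\.tsv$", ".json", summary_path),
               "json")
  invisible(results)
}

#' Run pair sub-classification over a selection report
#'
#' Consumes the rows of a [run_select()] report whose outcome left exactly
#' two competing candidates (a 2-2 majority tie, or an exclusion stage with
#' two survivors) and classifies each pair as near-identical, permuted or
#' divergent.
#'
#' @param config A [run_config()].
#' @param report_path Per-term report TSV from [run_select()].
#' @param out_path Output TSV.
#' @param gold_path,tokenizer As in [run_select()].
#' @return Invisibly, the output data.frame.
#' @export
run_pairs <- function(config, report_path, out_path, gold_path = NULL,
                      tokenizer = NULL) {
  rep_df <- read_report(report_path, "tsv")
  if (is.null(tokenizer)) {
    gold <- if (is.null(gold_path)) list() else read_gold_tokens(gold_path)
    tokenizer <- fixture_tokenizer(gold)
  }
  chosen <- strsplit(rep_df$chosen, "|", fixed = TRUE)
  keep <- rep_df$outcome %in% c("TWO_CANDIDATES_MAJORITY",
                                "MULTIPLE_EXCLUSION") &
    lengths(chosen) == 2L
  rows <- which(keep)
  out <- data.frame(
    term_id = rep_df$term_id[rows],
    label_a = vapply(chosen[rows], `[[`, character(1), 1L),
    label_b = vapply(chosen[rows], `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  verdicts <- lapply(seq_len(nrow(out)), function(i) {
    classify_pair(out$label_a[i], out$label_b[i], tokenizer = tokenizer,
                  stop_chars = config$stop_chars)
  })
  out$group <- vapply(verdicts, `[[`, character(1), "group")
  out$stripped_a <- vapply(verdicts, function(v) v$evidence$stripped_a,
                           character(1))
  out$stripped_b <- vapply(verdicts, function(v) v$evidence$stripped_b,
                           character(1))
  write_report(out, out_path, "tsv")
  invisible(out)
}

#' Run the harmonization workflow
#'
#' Reads a concept-equivalence map, classifies every pair on the
#' same/different grid, attaches recommended actions and writes the
#' per-pair report plus a summary (TSV and JSON).
#'
#' @param config A [run_config()] (`precedence_side`,
#'   `species_lexicon_path`).
#' @param pairs_path Equivalence-map TSV (see [read_equivalence_map()]).
#' @param out_path Per-pair report TSV.
#' @param summary_path Summary TSV (default `<out_path>.summary.tsv`).
#' @return Invisibly, the harmonized data.frame.
#' @export
run_harmonize <- function(config, pairs_path, out_path,
                          summary_path = NULL) {
  pairs <- read_equivalence_map(pairs_path)
  lexicon <- if (is.null(config$species_lexicon_path)) {
    default_species_lexicon()
  } else {
    read_species_lexicon(config$species_lexicon_path)
  }
  res <- harmonize_pairs(pairs, lexicon = lexicon,
                         precedence = config$precedence_side)
  write_report(res, out_path, "tsv")
  s <- summarize_harmonization(res)
  if (is.null(summary_path)) {
    summary_path <- paste0(out_path, ".summary.tsv")
  }
  write_report(summary_to_records(s), summary_path, "tsv")
  write_report(summary_to_records(s), sub("\\.tsv$", ".json", summary_path),
               "json")
  invisible(res)
}

#' Generate and write synthetic fixtures
#'
#' Writes `candidates.tsv`, `gold_tokens.tsv`, `selection_truth.tsv`,
#' `pairs.tsv` and `pair_truth.tsv` under `out_dir`.
#'
#' @param config A [run_config()] (sources, exempt sources, seed).
#' @param n Number of terms and of concept pairs.
#' @param out_dir Output directory (created if needed).
#' @param spec Optional [fixture_spec()] overriding `n` and `config$seed`.
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config, n = 500L, out_dir = ".", spec = NULL) {
  if (is.null(spec)) spec <- fixture_spec(n_terms = n, seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cand <- generate_candidates(spec, sources = config$sources,
                              exempt_sources = config$exempt_sources)
  prs <- generate_pairs(spec)
  paths <- file.path(out_dir, c("candidates.tsv", "gold_tokens.tsv",
                                "selection_truth.tsv", "pairs.tsv",
                                "pair_truth.tsv"))
  write_candidate_table(cand$candidates, paths[1])
  write_gold_tokens(cand$gold, paths[2])
  write_report(cand$truth, paths[3], "tsv")
  pair_df <- prs$pairs
  pair_df$label_ja_a[pair_df$ja_absent_a] <- ""
  pair_df$label_ja_b[pair_df$ja_absent_b] <- ""
  write_report(pair_df[, c("id_a", "id_b", "label_en_a", "label_en_b",
                           "label_ja_a", "label_ja_b")], paths[4], "tsv")
  write_report(prs$truth, paths[5], "tsv")
  invisible(stats::setNames(as.list(paths),
                            c("candidates", "gold_tokens", "selection_truth",
                              "pairs", "pair_truth")))
}
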
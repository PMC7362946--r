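test_that("simulate -> select -> pairs -> harmonize round trip on disk", {
  dir <- withr::local_tempdir()
  cfg <- run_config(seed = 11)
  paths <- run_simulate(cfg, n = 120, out_dir = dir)
  expect_true(all(file.exists(unlist(paths))))

  report <- file.path(dir, "report.tsv")
  results <- run_select(cfg, paths$candidates, report,
                        gold_path = paths$gold_tokens)

  # summary written to disk matches planted truth
  truth <- read_report(paths$selection_truth, "tsv")
  s <- read_report(paste0(report, ".summary.tsv"), "tsv")
  counts <- stats::setNames(as.integer(s$n), s$key)
  planted <- table(factor(truth$outcome, levels = selection_outcomes()))
  for (o in selection_outcomes()) {
    expect_equal(counts[[o]], unname(planted[[o]]))
  }
  # per-term report agrees with planted outcomes and chosen labels
  rep_df <- read_report(report, "tsv")
  expect_equal(rep_df$outcome, truth$outcome)
  expect_equal(rep_df$chosen, truth$chosen)

  # two-candidate rows classify without error
  pair_out <- file.path(dir, "pair_groups.tsv")
  pg <- run_pairs(cfg, report, pair_out, gold_path = paths$gold_tokens)
  expect_true(all(pg$group %in% c("NEAR_IDENTICAL", "PERMUTED", "DIVERGENT")))
  two_cand <- rep_df$term_id[
    rep_df$outcome %in% c("TWO_CANDIDATES_MAJORITY", "MULTIPLE_EXCLUSION") &
      lengths(strsplit(rep_df$chosen, "|", fixed = TRUE)) == 2L]
  expect_equal(pg$term_id, two_cand)

  # harmonization end-to-end against planted categories
  harm_out <- file.path(dir, "harmonized.tsv")
  hr <- run_harmonize(cfg, paths$pairs, harm_out)
  pair_truth <- read_report(paths$pair_truth, "tsv")
  expect_equal(hr$category, pair_truth$category)
})

test_that("re-running with identical inputs gives byte-identical reports", {
  dir <- withr::local_tempdir()
  cfg <- run_config(seed = 5)
  paths <- run_simulate(cfg, n = 40, out_dir = dir)
  r1 <- file.path(dir, "r1.tsv")
  r2 <- file.path(dir, "r2.tsv")
  run_select(cfg, paths$candidates, r1, gold_path = paths$gold_tokens)
  run_select(cfg, paths$candidates, r2, gold_path = paths$gold_tokens)
  expect_identical(readBin(r1, "raw", file.size(r1)),
                   readBin(r2, "raw", file.size(r2)))
})

test_that("an empty candidate table yields an empty report and zero summary", {
  dir <- withr::local_tempdir()
  cand <- file.path(dir, "cand.tsv")
  writeLines("term_id\tLSD\tMP\tEXPERT\tMT", cand)
  out <- file.path(dir, "report.tsv")
  results <- run_select(run_config(), cand, out)
  expect_length(results, 0L)
  s <- read_report(paste0(out, ".summary.tsv"), "tsv")
  expect_true(all(as.integer(s$n) == 0L))
})

test_that("reader contract errors surface from the workflow layer", {
  dir <- withr::local_tempdir()
  cand <- file.path(dir, "cand.tsv")
  writeLines(c("term_id\tLSD\tMP\tEXPERT", "T:1\ta\tb\tc"), cand)
  expect_error(run_select(run_config(), cand, file.path(dir, "out.tsv")),
               "MT")
})

test_that("degenerate harmonization input: all translations missing", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "equiv.tsv")
  writeLines(c("id_a\tid_b\tlabel_en_a\tlabel_en_b\tlabel_ja_a\tlabel_ja_b",
               "HP:1\tMP:1\tA\tA\t\t",
               "HP:2\tMP:2\tB\tC\t\t"), p)
  res <- run_harmonize(run_config(), p, file.path(dir, "harm.tsv"))
  expect_true(all(res$category == "NO_JA_CANDIDATE"))
  expect_true(all(res$action == "AWAIT_TRANSLATION"))
})

test_that("hand-written pairs hit each grid cell once", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "equiv.tsv")
  writeLines(c(
    "id_a\tid_b\tlabel_en_a\tlabel_en_b\tlabel_ja_a\tlabel_ja_b",
    "HP:1\tMP:1\tA\tA\tx\tx",
    "HP:2\tMP:2\tA\tA\tx\ty",
    "HP:3\tMP:3\tA\tB\tx\tx",
    "HP:4\tMP:4\tA\tB\tx\ty"
  ), p)
  res <- run_harmonize(run_config(), p, file.path(dir, "harm.tsv"))
  s <- unclass(summarize_harmonization(res))
  grid <- c("BOTH_SAME", "EN_SAME_ONLY", "JA_SAME_ONLY", "BOTH_DIFFERENT")
  expect_true(all(s[grid] == 1L))
})

test_that("config loading merges file values and overrides", {
  dir <- withr::local_tempdir()
  cfgf <- file.path(dir, "cfg.yaml")
  writeLines(c("stage_order: exclusion_first", "seed: 42"), cfgf)
  cfg <- load_run_config(cfgf)
  expect_equal(cfg$stage_order, "exclusion_first")
  expect_equal(cfg$seed, 42L)
  cfg2 <- load_run_config(cfgf, overrides = list(seed = 7))
  expect_equal(cfg2$seed, 7L)
  expect_error(load_run_config(cfgf, overrides = list(bogus = 1)),
               "unknown config key")
  expect_error(run_config(exempt_sources = "NOPE"), "subset")
})
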
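# Run configuration.
#
# Defaults reproduce the motivating four-source setup: sources LSD, MP,
# EXPERT, MT with the dictionary-combination source (LSD) exempt from
# morphological analysis, all six anomaly features active, and the majority
# stage before the exclusion stage.

#' Build a run configuration
#'
#' @param sources Ordered source tags of the candidate table.
#' @param exempt_sources Sources exempt from the exclusion stage (must be a
#'   subset of `sources`); they vote but are neither excludable nor
#'   survivable.
#' @param active_features Active anomaly features, a subset of
#'   [anomaly_features()].
#' @param stage_order `"majority_first"` (default) or `"exclusion_first"`
#'   (drop anomalous non-exempt candidates before voting).
#' @param stop_chars Stop characters for pair classification.
#' @param comma_codepoints Comma characters for the comma feature.
#' @param precedence_side `"a"` or `"b"`: which side's translation wins in
#'   harmonization when only the English labels agree.
#' @param species_lexicon_path Optional TSV path for a species-variant
#'   lexicon; NULL means [default_species_lexicon()].
#' @param seed Integer seed for simulation commands.
#' @return An object of class `run_config`.
#' @export
run_config <- function(sources = c("LSD", "MP", "EXPERT", "MT"),
                       exempt_sources = "LSD",
                       active_features = anomaly_features(),
                       stage_order = c("majority_first", "exclusion_first"),
                       stop_chars = "症",
                       comma_codepoints = ja_comma_chars(),
                       precedence_side = c("a", "b"),
                       species_lexicon_path = NULL,
                       seed = 1L) {
  stage_order <- match.arg(stage_order)
  precedence_side <- match.arg(precedence_side)
  if (!all(exempt_sources %in% sources)) {
    stop("exempt_sources must be a subset of sources", call. = FALSE)
  }
  bad <- setdiff(active_features, anomaly_features())
  if (length(bad)) {
    stop("unknown feature(s) in active_features: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(sources = sources, exempt_sources = exempt_sources,
         active_features = active_features, stage_order = stage_order,
         stop_chars = stop_chars, comma_codepoints = comma_codepoints,
         precedence_side = precedence_side,
         species_lexicon_path = species_lexicon_path,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Load a run configuration from a flat YAML file
#'
#' The file holds flat keys matching the arguments of [run_config()];
#' anything not present keeps its default. `overrides` (typically parsed
#' CLI flags) win over file values.
#'
#' @param path Path to a YAML config file, or NULL for pure defaults.
#' @param overrides Named list of run_config arguments taking precedence.
#' @return A [run_config()].
#' @export
load_run_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    vals <- yaml::read_yaml(path)
    if (is.null(vals)) vals <- list()
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}
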
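# Tabular I/O for the curation pipeline.
#
# All TSV files share one dialect: UTF-8, tab-separated, header row required,
# backslash escapes (\t, \n, \r, \\) for the rare embedded tab/newline in a
# label. Comma-separated files are unsafe here because Japanese labels may
# contain U+3001/U+FF0C commas.

tsv_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

tsv_unescape <- function(x) {
  # single left-to-right pass so "\\t" decodes to a literal backslash + t
  vapply(x, function(s) {
    if (!grepl("\\", s, fixed = TRUE)) return(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    out <- character(0)
    i <- 1L
    n <- length(chars)
    while (i <= n) {
      if (chars[i] == "\\" && i < n) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt, t = "\t", n = "\n", r = "\r",
                             "\\" = "\\", paste0("\\", nxt)))
        i <- i + 2L
      } else {
        out <- c(out, chars[i])
        i <- i + 1L
      }
    }
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

tsv_write <- function(df, path) {
  stopifnot(is.data.frame(df))
  cols <- lapply(df, function(col) tsv_escape(as.character(col)))
  body <- if (nrow(df)) do.call(paste, c(cols, sep = "\t")) else character(0)
  lines <- c(paste(tsv_escape(names(df)), collapse = "\t"), body)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

tsv_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty file (header required): ", path,
                                call. = FALSE)
  split_row <- function(line) tsv_unescape(strsplit(line, "\t",
                                                    fixed = TRUE)[[1L]])
  header <- split_row(lines[1L])
  body <- lines[-1L]
  body <- body[nzchar(body)]
  ncol <- length(header)
  rows <- lapply(seq_along(body), function(i) {
    fields <- strsplit(body[[i]], "\t", fixed = TRUE)[[1L]]
    # a trailing empty field is dropped by strsplit; pad it back
    if (length(fields) < ncol) fields <- c(fields, rep("", ncol - length(fields)))
    if (length(fields) != ncol) {
      stop("malformed row at line ", i + 1L, " of ", path, ": expected ",
           ncol, " fields, got ", length(fields), call. = FALSE)
    }
    tsv_unescape(fields)
  })
  out <- as.data.frame(
    stats::setNames(
      lapply(seq_len(ncol), function(j)
        vapply(rows, `[[`, character(1), j)),
      header
    ),
    stringsAsFactors = FALSE, check.names = FALSE
  )
  if (length(rows) == 0L) {
    out <- as.data.frame(stats::setNames(rep(list(character(0)), ncol), header),
                         stringsAsFactors = FALSE, check.names = FALSE)
  }
  out
}

#' Read an ontology term table
#'
#' Reads term identifiers and English labels either from a two-column TSV
#' (`term_id`, `label_en`, header required) or from an OBO file, of which
#' only the `id:` and `name:` fields of `[Term]` stanzas are used.
#'
#' @param path Path to the input file.
#' @param format `"tsv"` or `"obo"`.
#' @param allow_empty_label Permit empty English labels (default FALSE).
#' @return A data.frame with character columns `term_id` and `label_en`,
#'   in input order. Duplicate term ids are an error.
#' @export
read_terms <- function(path, format = c("tsv", "obo"),
                       allow_empty_label = FALSE) {
  format <- match.arg(format)
  terms <- if (format == "tsv") read_terms_tsv(path) else read_terms_obo(path)
  dup <- unique(terms$term_id[duplicated(terms$term_id)])
  if (length(dup)) {
    stop("duplicate term_id in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(terms$term_id))) {
    stop("empty term_id in ", path, call. = FALSE)
  }
  if (!allow_empty_label && any(!nzchar(terms$label_en))) {
    stop("empty label_en in ", path,
         " (set allow_empty_label = TRUE to permit)", call. = FALSE)
  }
  terms
}

read_terms_tsv <- function(path) {
  df <- tsv_read(path)
  if (ncol(df) != 2L) {
    stop("term TSV must have exactly 2 columns, got ", ncol(df), " in ",
         path, call. = FALSE)
  }
  names(df) <- c("term_id", "label_en")
  df
}

read_terms_obo <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  in_term <- FALSE
  stanza_line <- 0L
  id <- NA_character_
  name <- NA_character_
  ids <- character()
  names_ <- character()
  flush <- function() {
    if (!in_term) return()
    if (is.na(id)) {
      stop("malformed [Term] stanza at line ", stanza_line, " of ", path,
           ": missing id", call. = FALSE)
    }
    ids <<- c(ids, id)
    names_ <<- c(names_, if (is.na(name)) "" else name)
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (grepl("^\\[", line)) {
      flush()
      in_term <- line == "[Term]"
      stanza_line <- i
      id <- NA_character_
      name <- NA_character_
    } else if (in_term && grepl("^id:", line)) {
      id <- trimws(sub("^id:", "", line))
    } else if (in_term && grepl("^name:", line)) {
      name <- trimws(sub("^name:", "", line))
    }
  }
  flush()
  data.frame(term_id = ids, label_en = names_, stringsAsFactors = FALSE)
}

#' Construct a candidate set
#'
#' One term's candidate translations, one per source, in source order.
#' Missing candidates are represented as empty strings.
#'
#' @param term_id Term identifier (CURIE string).
#' @param labels Character vector of raw candidate labels, one per source.
#' @param sources Character vector of source tags (unique), defaults to
#'   `names(labels)`.
#' @return An object of class `candidate_set`.
#' @export
candidate_set <- function(term_id, labels, sources = names(labels)) {
  labels <- as.character(labels)
  if (is.null(sources)) {
    stop("sources must be supplied (or labels named)", call. = FALSE)
  }
  if (length(sources) != length(labels)) {
    stop("labels and sources length mismatch", call. = FALSE)
  }
  if (anyDuplicated(sources)) {
    stop("duplicate source tags: ",
         paste(unique(sources[duplicated(sources)]), collapse = ", "),
         call. = FALSE)
  }
  labels[is.na(labels)] <- ""
  structure(
    list(term_id = as.character(term_id), sources = as.character(sources),
         labels = unname(labels)),
    class = "candidate_set"
  )
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("<candidate_set ", x$term_id, ">\n", sep = "")
  for (i in seq_along(x$sources)) {
    cat("  ", format(x$sources[i], width = 8), " ",
        if (nzchar(x$labels[i])) x$labels[i] else "<blank>", "\n", sep = "")
  }
  invisible(x)
}

#' Read a candidate translation table
#'
#' @param path TSV with a `term_id` column plus one column per source tag.
#' @param sources Character vector of expected source columns.
#' @return A list of [candidate_set] objects, one per row, in input order.
#'   Absent cells become empty strings.
#' @export
read_candidate_table <- function(path, sources) {
  df <- tsv_read(path)
  if (!"term_id" %in% names(df)) {
    stop("missing column 'term_id' in ", path, call. = FALSE)
  }
  missing <- setdiff(sources, names(df))
  if (length(missing)) {
    stop("missing source column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    candidate_set(df$term_id[i],
                  labels = vapply(sources, function(s) df[[s]][i],
                                  character(1)),
                  sources = sources)
  })
}

#' Write a candidate table
#'
#' Inverse of [read_candidate_table()]: one row per candidate set, a
#' `term_id` column plus one column per source.
#'
#' @param sets List of [candidate_set] objects sharing the same sources.
#' @param path Output TSV path.
#' @export
write_candidate_table <- function(sets, path) {
  if (length(sets) == 0L) {
    stop("cannot infer sources from an empty set list", call. = FALSE)
  }
  sources <- sets[[1L]]$sources
  df <- data.frame(term_id = vapply(sets, `[[`, character(1), "term_id"),
                   stringsAsFactors = FALSE)
  for (j in seq_along(sources)) {
    df[[sources[j]]] <- vapply(sets, function(s) s$labels[j], character(1))
  }
  tsv_write(df, path)
}

#' Read a concept-equivalence map between two ontologies
#'
#' Expects TSV columns `id_a`, `id_b`, `label_en_a`, `label_en_b`,
#' `label_ja_a`, `label_ja_b`. An empty translated-label cell means the
#' translation does not exist yet; this absence is recorded in the logical
#' columns `ja_absent_a` / `ja_absent_b` and kept distinct from a label that
#' merely normalizes to the empty string.
#'
#' @param path Input TSV path.
#' @return A data.frame of pairs in input order with the six input columns
#'   plus the two absence flags.
#' @export
read_equivalence_map <- function(path) {
  df <- tsv_read(path)
  need <- c("id_a", "id_b", "label_en_a", "label_en_b",
            "label_ja_a", "label_ja_b")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- which(!nzchar(df$id_a) | !nzchar(df$id_b))
  if (length(bad)) {
    stop("missing concept id at line ", bad[1L] + 1L, " of ", path,
         call. = FALSE)
  }
  df$ja_absent_a <- !nzchar(df$label_ja_a)
  df$ja_absent_b <- !nzchar(df$label_ja_b)
  df[, c(need, "ja_absent_a", "ja_absent_b")]
}

#' Write a report table
#'
#' Writes a flat record table as TSV (package dialect, see
#' [read_report()]) or as a JSON array of flat objects. Writing then
#' re-reading reproduces the records field-exactly.
#'
#' @param records A data.frame of records (coerced to character fields).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @export
write_report <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(records))
  records[] <- lapply(records, as.character)
  if (format == "tsv") {
    tsv_write(records, path)
  } else {
    jsonlite::write_json(records, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a report table
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"`.
#' @return A data.frame with all-character columns.
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tsv_read(path)
  } else {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L) return(data.frame())
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    df[] <- lapply(df, as.character)
    df
  }
}
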
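# Corpus container and I/O. A corpus is a column-oriented list (class
# "ms_corpus"): id and text character vectors, optional category labels,
# and -- once preprocessed -- parallel lists of tokens and summary_tokens.

#' Construct a document corpus
#'
#' @param id character vector of unique document identifiers.
#' @param text character vector of raw free text, same length.
#' @param category optional character vector of reference labels.
#' @return an `ms_corpus` object.
#' @export
ms_corpus <- function(id, text, category = NULL) {
  id <- as.character(id)
  text <- as.character(text)
  if (length(id) != length(text)) stop("id and text lengths differ")
  if (anyDuplicated(id)) stop("duplicate document ids")
  if (!is.null(category)) {
    category <- as.character(category)
    if (length(category) != length(id)) stop("category length differs")
  }
  structure(list(id = id, text = text, category = category,
                 tokens = NULL, summary_tokens = NULL),
            class = "ms_corpus")
}

#' @export
print.ms_corpus <- function(x, ...) {
  cat("ms_corpus:", length(x$id), "documents",
      if (!is.null(x$tokens)) "(preprocessed)" else "(raw)",
      if (!is.null(x$category)) sprintf("| %d categories",
                                        length(unique(x$category))) else "",
      "\n")
  invisible(x)
}

#' @export
length.ms_corpus <- function(x) length(x$id)

#' Read a corpus from JSONL or CSV
#'
#' JSONL files hold one object per line with fields `id`, `text` and
#' optionally `category`; CSV files the same columns. The format is chosen
#' from the file extension (`.jsonl`/`.json` vs `.csv`).
#'
#' @param path file path (UTF-8).
#' @return an `ms_corpus`.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character", encoding = "UTF-8")
    if (!all(c("id", "text") %in% names(df)))
      stop("CSV corpus must have columns id, text")
    return(ms_corpus(df$id, df$text,
                     if ("category" %in% names(df)) df$category else NULL))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  ids <- vapply(recs, function(r) as.character(r$id), character(1))
  txt <- vapply(recs, function(r) as.character(r$text), character(1))
  cats <- vapply(recs, function(r)
    if (is.null(r$category)) NA_character_ else as.character(r$category),
    character(1))
  ms_corpus(ids, txt, if (all(is.na(cats))) NULL else cats)
}

#' Preprocess a corpus in place
#'
#' Fills the `tokens` (normalised, stemmed, stop-word-filtered) and
#' `summary_tokens` (lemmatised content words) fields of every document.
#'
#' @param corpus an `ms_corpus`.
#' @param stoplist stop-word vector; default [stopwords_en()].
#' @param extra_excluded_verbs passed to [summary_tokens()].
#' @param stop_match passed to [normalize_tokens()].
#' @return the corpus with token fields populated.
#' @export
preprocess_corpus <- function(corpus, stoplist = stopwords_en(),
                              extra_excluded_verbs = character(0),
                              stop_match = "both") {
  stopifnot(inherits(corpus, "ms_corpus"))
  corpus$tokens <- lapply(corpus$text, normalize_tokens,
                          stoplist = stoplist, stop_match = stop_match)
  corpus$summary_tokens <- lapply(corpus$text, summary_tokens,
                                  extra_excluded_verbs = extra_excluded_verbs)
  names(corpus$tokens) <- corpus$id
  names(corpus$summary_tokens) <- corpus$id
  corpus
}

#' Write a tokenised corpus as JSONL
#'
#' One object per line: `id`, `tokens`, `summary_tokens`.
#'
#' @param corpus a preprocessed `ms_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tokens_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "ms_corpus"), !is.null(corpus$tokens))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(corpus$id)) {
    writeLines(jsonlite::toJSON(list(
      id = jsonlite::unbox(corpus$id[i]),
      tokens = corpus$tokens[[i]],
      summary_tokens = corpus$summary_tokens[[i]]), null = "null"), con)
  }
  invisible(path)
}

#' Write a corpus as JSONL
#'
#' One object per line: `id`, `text`, and `category` when present.
#'
#' @param corpus an `ms_corpus`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "ms_corpus"))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_along(corpus$id)) {
    rec <- list(id = jsonlite::unbox(corpus$id[i]),
                text = jsonlite::unbox(corpus$text[i]))
    if (!is.null(corpus$category))
      rec$category <- jsonlite::unbox(corpus$category[i])
    writeLines(jsonlite::toJSON(rec, null = "null"), con)
  }
  invisible(path)
}
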
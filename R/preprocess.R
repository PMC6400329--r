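# Text normalisation: tokenise, stem, stop-word removal for the embedding
# path; rule-based content-word filtering + lemmatisation for the
# human-readable summary path.

#' English stop-word list
#'
#' The standard 127-word English stop list commonly used in text mining
#' (articles, pronouns, auxiliaries, prepositions, common particles).
#'
#' @return character vector of stop words.
#' @export
stopwords_en <- function() {
  c("i", "me", "my", "myself", "we", "our", "ours", "ourselves", "you",
    "your", "yours", "yourself", "yourselves", "he", "him", "his",
    "himself", "she", "her", "hers", "herself", "it", "its", "itself",
    "they", "them", "their", "theirs", "themselves", "what", "which",
    "who", "whom", "this", "that", "these", "those", "am", "is", "are",
    "was", "were", "be", "been", "being", "have", "has", "had", "having",
    "do", "does", "did", "doing", "a", "an", "the", "and", "but", "if",
    "or", "because", "as", "until", "while", "of", "at", "by", "for",
    "with", "about", "against", "between", "into", "through", "during",
    "before", "after", "above", "below", "to", "from", "up", "down", "in",
    "out", "on", "off", "over", "under", "again", "further", "then",
    "once", "here", "there", "when", "where", "why", "how", "all", "any",
    "both", "each", "few", "more", "most", "other", "some", "such", "no",
    "nor", "not", "only", "own", "same", "so", "than", "too", "very", "s",
    "t", "can", "will", "just", "don", "should", "now")
}

# lowercase word tokenisation: runs of ASCII letters/digits; digit-only and
# punctuation-only tokens dropped
.tokenize_raw <- function(text) {
  toks <- regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
  toks[!grepl("^[0-9]+$", toks)]
}

#' Normalise raw text into stemmed tokens
#'
#' Lowercases, tokenises into alphanumeric word tokens, drops punctuation
#' and digit-only tokens, stems each token with the Porter algorithm, and
#' removes stop words. Stop words are by default matched against both the
#' raw and the stemmed form of every token (and the stop list itself is
#' also stemmed), so that no stemmed variant of a stop word leaks through;
#' `stop_match = "pre"` restricts matching to raw tokens only,
#' `"post"` to stemmed tokens only.
#'
#' @param text a character string (possibly empty).
#' @param stoplist character vector of stop words; default [stopwords_en()].
#' @param stop_match one of `"both"` (default), `"pre"`, `"post"`.
#' @return character vector of surviving stemmed tokens, in input order.
#' @examples
#' normalize_tokens("Patient was given 500 paracetamol tablets!")
#' @export
normalize_tokens <- function(text, stoplist = stopwords_en(),
                             stop_match = c("both", "pre", "post")) {
  stop_match <- match.arg(stop_match)
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character(0))
  raw <- .tokenize_raw(text)
  if (length(raw) == 0L) return(character(0))
  stems <- porter_stem(raw)
  stopset <- unique(c(stoplist, porter_stem(stoplist)))
  keep <- switch(stop_match,
    pre  = !(raw %in% stoplist),
    post = !(stems %in% stopset),
    both = !(raw %in% stopset) & !(stems %in% stopset))
  stems[keep]
}

# closed-class function words for the content-word (summary) path: the stop
# list plus modals and a few frequent particles not in it
.function_words <- function() {
  unique(c(stopwords_en(),
           c("shall", "must", "might", "may", "could", "would", "cannot",
             "also", "via", "per", "upon", "within", "without", "onto",
             "among", "amongst", "whilst", "although", "though", "unless",
             "whether", "since", "yet", "etc", "eg", "ie")))
}

# inflections of the excluded common verbs be/have/do
.excluded_verb_forms <- function(extra = character(0)) {
  base <- c("be", "am", "is", "are", "was", "were", "been", "being",
            "have", "has", "had", "having", "do", "does", "did", "doing",
            "done")
  if (length(extra)) {
    infl <- unlist(lapply(extra, function(v) {
      c(v, paste0(v, "s"), paste0(v, "es"), paste0(v, "ed"),
        paste0(v, "ing"))
    }))
    base <- c(base, infl)
  }
  unique(base)
}

# suffix-rule lemmatiser for alphabetic English tokens; identifiers with
# digits are passed through untouched
.lemmatize <- function(tok) {
  if (grepl("[^a-z]", tok) || nchar(tok) <= 3L) return(tok)
  n <- nchar(tok)
  ends <- function(s) {
    k <- nchar(s)
    n >= k && substr(tok, n - k + 1L, n) == s
  }
  chop <- function(k) substr(tok, 1L, n - k)
  has_double <- function(w) {
    m <- nchar(w)
    m >= 2L && substr(w, m, m) == substr(w, m - 1L, m - 1L) &&
      !substr(w, m, m) %in% c("l", "s", "z")
  }
  # undoubling (hopped -> hop) and e-restoration (making -> make) are
  # mutually exclusive, as in Porter step 1b; e is restored only for
  # short (measure-1) stems ending consonant-vowel-consonant
  destem <- function(w) {
    if (!.p_has_vowel(w)) return(tok)
    if (has_double(w)) return(substr(w, 1L, nchar(w) - 1L))
    if (.p_measure(w) == 1L && .p_ends_cvc(w)) return(paste0(w, "e"))
    w
  }
  # nominal plurals
  if (ends("ies") && n > 4L) return(paste0(chop(3L), "y"))
  if (ends("sses")) return(chop(2L))
  if (ends("xes") || ends("ches") || ends("shes") || ends("zes"))
    return(chop(2L))
  if (ends("ses")) return(chop(1L))
  if (ends("s") && !ends("ss") && !ends("us") && !ends("is"))
    return(chop(1L))
  # verbal inflections
  if (ends("ing") && n > 5L) return(destem(chop(3L)))
  if (ends("ied") && n > 4L) return(paste0(chop(3L), "y"))
  if (ends("ed") && n > 4L) return(destem(chop(2L)))
  tok
}

#' Content-word lemmas for human-readable summaries
#'
#' Extracts the content words (adjectives, nouns, verbs) of a text for word
#' clouds and n-gram summaries. A rule-based tagger is used: closed-class
#' function words and "-ly" adverbs are removed, as are the low-content
#' verbs *be*, *have* and *do* with all their inflections (plus any verbs
#' listed in `extra_excluded_verbs`); the survivors are lemmatised with
#' suffix rules (plural and verbal inflections stripped). Tokens containing
#' digits (codes, identifiers) are kept untouched.
#'
#' @param text a character string.
#' @param extra_excluded_verbs additional verb lemmas to exclude along with
#'   their regular inflections.
#' @return character vector of lemmas, in input order.
#' @examples
#' summary_tokens("nurses were transferring patients")
#' @export
summary_tokens <- function(text, extra_excluded_verbs = character(0)) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(character(0))
  toks <- .tokenize_raw(text)
  if (length(toks) == 0L) return(character(0))
  drop <- toks %in% .function_words() |
    toks %in% .excluded_verb_forms(extra_excluded_verbs) |
    (grepl("ly$", toks) & nchar(toks) > 4L & !grepl("[0-9]", toks))
  toks <- toks[!drop]
  vapply(toks, .lemmatize, character(1), USE.NAMES = FALSE)
}

#' Pooled n-gram frequencies over summary tokens
#'
#' Counts contiguous n-grams (for every n in `n_range`) over the
#' `summary_tokens` of a set of documents, pooled across documents and
#' sorted by descending count. N-grams are represented as space-joined
#' strings.
#'
#' @param docs an `ms_corpus`, or a list of character token vectors.
#' @param n_range integer pair `c(n_min, n_max)` with
#'   `1 <= n_min <= n_max <= 3`.
#' @return named integer vector of counts, sorted descending (ties in
#'   lexicographic order).
#' @export
ngram_frequencies <- function(docs, n_range = c(2L, 3L)) {
  stopifnot(length(n_range) == 2L, n_range[1] >= 1L,
            n_range[1] <= n_range[2], n_range[2] <= 3L)
  toks <- .as_token_list(docs, "summary_tokens")
  grams <- character(0)
  for (tt in toks) {
    L <- length(tt)
    for (n in seq(n_range[1], n_range[2])) {
      if (L < n) next
      idx <- seq_len(L - n + 1L)
      g <- tt[idx]
      if (n >= 2L) for (j in 2:n) g <- paste(g, tt[idx + j - 1L])
      grams <- c(grams, g)
    }
  }
  if (length(grams) == 0L) return(integer(0))
  tab <- table(grams)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[order(-counts, names(counts))]
}

# coerce corpus-like input to a list of token vectors
.as_token_list <- function(docs, field = c("tokens", "summary_tokens")) {
  field <- match.arg(field)
  if (inherits(docs, "ms_corpus")) return(docs[[field]])
  if (is.list(docs)) return(lapply(docs, as.character))
  stop("expected an ms_corpus or a list of token vectors")
}
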
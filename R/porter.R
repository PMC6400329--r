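# Porter (1980) stemming algorithm, implemented directly from the published
# rule tables. Words are assumed lowercase ASCII; words of length <= 2 are
# returned unchanged. Longest-suffix matching within each step: if the
# condition of the longest matching rule fails, no shorter rule of that step
# is tried.

# consonant test at position i (1-based): y is a vowel iff preceded by a
# consonant; a leading y is a consonant.
.p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.p_is_cons(chars, i - 1L))
  }
  TRUE
}

# measure m of a stem: [C](VC)^m[V]
.p_measure <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(0L)
  types <- vapply(seq_len(n), function(i) .p_is_cons(chars, i), logical(1))
  # collapse runs; count V->C transitions
  runs <- rle(types)$values
  sum(runs == TRUE & seq_along(runs) > 1L & c(FALSE, head(runs, -1L)) == FALSE)
}

.p_has_vowel <- function(stem) {
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n == 0L) return(FALSE)
  any(!vapply(seq_len(n), function(i) .p_is_cons(chars, i), logical(1)))
}

.p_double_cons <- function(stem) {
  n <- nchar(stem)
  if (n < 2L) return(FALSE)
  a <- substr(stem, n - 1L, n - 1L)
  b <- substr(stem, n, n)
  if (a != b) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  .p_is_cons(chars, n)
}

# *o: stem ends cvc where the final c is not w, x or y
.p_ends_cvc <- function(stem) {
  n <- nchar(stem)
  if (n < 3L) return(FALSE)
  chars <- strsplit(stem, "", fixed = TRUE)[[1]]
  if (!.p_is_cons(chars, n)) return(FALSE)
  if (.p_is_cons(chars, n - 1L)) return(FALSE)
  if (!.p_is_cons(chars, n - 2L)) return(FALSE)
  !(chars[n] %in% c("w", "x", "y"))
}

.p_ends <- function(word, suffix) {
  n <- nchar(word); k <- nchar(suffix)
  n >= k && substr(word, n - k + 1L, n) == suffix
}

.p_chop <- function(word, k) substr(word, 1L, nchar(word) - k)

.porter_step1a <- function(w) {
  if (.p_ends(w, "sses")) return(.p_chop(w, 2L))
  if (.p_ends(w, "ies"))  return(.p_chop(w, 2L))
  if (.p_ends(w, "ss"))   return(w)
  if (.p_ends(w, "s"))    return(.p_chop(w, 1L))
  w
}

.porter_step1b <- function(w) {
  if (.p_ends(w, "eed")) {
    stem <- .p_chop(w, 3L)
    if (.p_measure(stem) > 0L) return(.p_chop(w, 1L))
    return(w)
  }
  fired <- FALSE
  if (.p_ends(w, "ed")) {
    stem <- .p_chop(w, 2L)
    if (.p_has_vowel(stem)) { w <- stem; fired <- TRUE }
  } else if (.p_ends(w, "ing")) {
    stem <- .p_chop(w, 3L)
    if (.p_has_vowel(stem)) { w <- stem; fired <- TRUE }
  }
  if (fired) {
    if (.p_ends(w, "at") || .p_ends(w, "bl") || .p_ends(w, "iz")) {
      w <- paste0(w, "e")
    } else if (.p_double_cons(w) &&
               !(.p_ends(w, "l") || .p_ends(w, "s") || .p_ends(w, "z"))) {
      w <- .p_chop(w, 1L)
    } else if (.p_measure(w) == 1L && .p_ends_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  w
}

.porter_step1c <- function(w) {
  if (.p_ends(w, "y") && .p_has_vowel(.p_chop(w, 1L)))
    return(paste0(.p_chop(w, 1L), "i"))
  w
}

# suffix tables for steps 2-4: list of c(suffix, replacement)
.porter_s2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)
.porter_s3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)
.porter_s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant",
                "ement", "ment", "ent", "ion", "ou", "ism", "ate", "iti",
                "ous", "ive", "ize")

.porter_replace <- function(w, table, min_m) {
  # longest matching suffix wins; condition tested only on that match
  lens <- vapply(table, function(r) nchar(r[1]), integer(1))
  ord <- order(lens, decreasing = TRUE)
  for (i in ord) {
    suf <- table[[i]][1]
    if (.p_ends(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      if (.p_measure(stem) > min_m) return(paste0(stem, table[[i]][2]))
      return(w)
    }
  }
  w
}

.porter_step4 <- function(w) {
  lens <- nchar(.porter_s4)
  ord <- order(lens, decreasing = TRUE)
  for (i in ord) {
    suf <- .porter_s4[i]
    if (.p_ends(w, suf)) {
      stem <- .p_chop(w, nchar(suf))
      if (.p_measure(stem) > 1L) {
        if (suf == "ion" &&
            !(.p_ends(stem, "s") || .p_ends(stem, "t"))) return(w)
        return(stem)
      }
      return(w)
    }
  }
  w
}

.porter_step5 <- function(w) {
  if (.p_ends(w, "e")) {
    stem <- .p_chop(w, 1L)
    m <- .p_measure(stem)
    if (m > 1L || (m == 1L && !.p_ends_cvc(stem))) w <- stem
  }
  if (.p_measure(w) > 1L && .p_double_cons(w) && .p_ends(w, "l"))
    w <- .p_chop(w, 1L)
  w
}

#' Porter stemmer
#'
#' Reduces English words to their stems with the classic Porter suffix-
#' stripping algorithm. Input is lowercased; words of one or two characters
#' are returned unchanged, as are tokens containing non-alphabetic
#' characters (identifiers, alphanumeric codes).
#'
#' @param words character vector of words.
#' @return character vector of stems, same length and order.
#' @examples
#' porter_stem(c("tablets", "relational", "happiness"))
#' @export
porter_stem <- function(words) {
  vapply(tolower(words), function(w) {
    if (nchar(w) <= 2L || grepl("[^a-z]", w)) return(w)
    w <- .porter_step1a(w)
    w <- .porter_step1b(w)
    w <- .porter_step1c(w)
    w <- .porter_replace(w, .porter_s2, 0L)
    w <- .porter_replace(w, .porter_s3, 0L)
    w <- .porter_step4(w)
    .porter_step5(w)
  }, character(1), USE.NAMES = FALSE)
}
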
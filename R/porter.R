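# Original Porter (1980) suffix-stripping stemmer.
#
# Implemented from the algorithm definition: a word is viewed as [C](VC)^m[V];
# each step strips the longest matching suffix whose condition on the remaining
# stem holds. 'y' counts as a vowel when preceded by a consonant.

.pt_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1L) return(TRUE)
    return(!.pt_is_cons(chars, i - 1L))
  }
  TRUE
}

# consonant/vowel mask for a word, TRUE = consonant
.pt_mask <- function(word) {
  chars <- strsplit(word, "", fixed = TRUE)[[1]]
  n <- length(chars)
  m <- logical(n)
  for (i in seq_len(n)) m[i] <- .pt_is_cons(chars, i)
  m
}

# measure m of [C](VC)^m[V]
.pt_measure <- function(word) {
  msk <- .pt_mask(word)
  if (length(msk) == 0L) return(0L)
  # collapse runs, count VC transitions
  runs <- rle(msk)$values
  sum(runs[-length(runs)] == FALSE & runs[-1] == TRUE)
}

.pt_has_vowel <- function(word) any(!.pt_mask(word))

.pt_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2L) return(FALSE)
  a <- substr(word, n - 1L, n - 1L)
  b <- substr(word, n, n)
  if (a != b) return(FALSE)
  msk <- .pt_mask(word)
  msk[n]
}

# *o: stem ends cvc where the final c is not w, x or y
.pt_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3L) return(FALSE)
  msk <- .pt_mask(word)
  if (!(msk[n - 2L] && !msk[n - 1L] && msk[n])) return(FALSE)
  !substr(word, n, n) %in% c("w", "x", "y")
}

.pt_ends <- function(word, suffix) {
  n <- nchar(word); s <- nchar(suffix)
  n > s && substr(word, n - s + 1L, n) == suffix
}

.pt_chop <- function(word, k) substr(word, 1L, nchar(word) - k)

.pt_step1ab <- function(w) {
  # step 1a
  if (.pt_ends(w, "sses")) {
    w <- .pt_chop(w, 2L)
  } else if (.pt_ends(w, "ies")) {
    w <- .pt_chop(w, 2L)
  } else if (!.pt_ends(w, "ss") && .pt_ends(w, "s")) {
    w <- .pt_chop(w, 1L)
  }
  # step 1b
  if (.pt_ends(w, "eed")) {
    if (.pt_measure(.pt_chop(w, 3L)) > 0L) w <- .pt_chop(w, 1L)
  } else {
    fired <- FALSE
    if (.pt_ends(w, "ed") && .pt_has_vowel(.pt_chop(w, 2L))) {
      w <- .pt_chop(w, 2L); fired <- TRUE
    } else if (.pt_ends(w, "ing") && .pt_has_vowel(.pt_chop(w, 3L))) {
      w <- .pt_chop(w, 3L); fired <- TRUE
    }
    if (fired) {
      last <- substr(w, nchar(w), nchar(w))
      if (.pt_ends(w, "at") || .pt_ends(w, "bl") || .pt_ends(w, "iz")) {
        w <- paste0(w, "e")
      } else if (.pt_double_cons(w) && !last %in% c("l", "s", "z")) {
        w <- .pt_chop(w, 1L)
      } else if (.pt_measure(w) == 1L && .pt_cvc(w)) {
        w <- paste0(w, "e")
      }
    }
  }
  w
}

.pt_step1c <- function(w) {
  if (.pt_ends(w, "y") && .pt_has_vowel(.pt_chop(w, 1L))) w <- paste0(.pt_chop(w, 1L), "i")
  w
}

# (suffix, replacement) pairs, longest suffix wins; condition m(stem) > 0
.pt_s2 <- list(
  c("ational", "ate"), c("tional", "tion"), c("enci", "ence"), c("anci", "ance"),
  c("izer", "ize"), c("abli", "able"), c("alli", "al"), c("entli", "ent"),
  c("eli", "e"), c("ousli", "ous"), c("ization", "ize"), c("ation", "ate"),
  c("ator", "ate"), c("alism", "al"), c("iveness", "ive"), c("fulness", "ful"),
  c("ousness", "ous"), c("aliti", "al"), c("iviti", "ive"), c("biliti", "ble")
)

.pt_s3 <- list(
  c("icate", "ic"), c("ative", ""), c("alize", "al"), c("iciti", "ic"),
  c("ical", "ic"), c("ful", ""), c("ness", "")
)

.pt_step23 <- function(w, rules) {
  # longest matching suffix decides; condition checked afterwards
  best <- NULL
  for (r in rules) {
    if (.pt_ends(w, r[1]) && (is.null(best) || nchar(r[1]) > nchar(best[1]))) best <- r
  }
  if (!is.null(best)) {
    stem <- .pt_chop(w, nchar(best[1]))
    if (.pt_measure(stem) > 0L) w <- paste0(stem, best[2])
  }
  w
}

.pt_s4 <- c("al", "ance", "ence", "er", "ic", "able", "ible", "ant", "ement",
            "ment", "ent", "ion", "ou", "ism", "ate", "iti", "ous", "ive", "ize")

.pt_step4 <- function(w) {
  best <- ""
  for (s in .pt_s4) if (.pt_ends(w, s) && nchar(s) > nchar(best)) best <- s
  if (nchar(best) > 0L) {
    stem <- .pt_chop(w, nchar(best))
    ok <- .pt_measure(stem) > 1L
    if (ok && best == "ion") {
      last <- substr(stem, nchar(stem), nchar(stem))
      ok <- last %in% c("s", "t")
    }
    if (ok) w <- stem
  }
  w
}

.pt_step5 <- function(w) {
  if (.pt_ends(w, "e")) {
    stem <- .pt_chop(w, 1L)
    m <- .pt_measure(stem)
    if (m > 1L || (m == 1L && !.pt_cvc(stem))) w <- stem
  }
  if (.pt_measure(w) > 1L && .pt_double_cons(w) &&
      substr(w, nchar(w), nchar(w)) == "l") {
    w <- .pt_chop(w, 1L)
  }
  w
}

.pt_stem_one <- function(word) {
  if (nchar(word) <= 2L) return(word)  # short words left alone, per the algorithm
  w <- .pt_step1ab(word)
  w <- .pt_step1c(w)
  w <- .pt_step23(w, .pt_s2)
  w <- .pt_step23(w, .pt_s3)
  w <- .pt_step4(w)
  .pt_step5(w)
}

.pt_cache <- new.env(parent = emptyenv())

#' Porter stem a vector of words
#'
#' Applies the original Porter suffix-stripping algorithm to each word.
#' Input is lowercased first; tokens containing characters outside `a-z`
#' (hashtags, numbers, emoji) are returned unchanged, since the algorithm is
#' defined only for alphabetic English words. Results are memoised across
#' calls, which makes stemming large corpora with bounded vocabularies cheap.
#'
#' @param words character vector.
#' @return character vector of stems, same length and order as `words`.
#' @examples
#' porter_stem(c("headaches", "running", "runner", "caresses"))
#' @export
porter_stem <- function(words) {
  if (length(words) == 0L) return(character(0))
  words <- stringi::stri_trans_tolower(words)
  uniq <- unique(words)
  known <- vapply(uniq, function(w) exists(w, envir = .pt_cache, inherits = FALSE),
                  logical(1))
  for (w in uniq[!known]) {
    s <- if (grepl("^[a-z]+$", w)) .pt_stem_one(w) else w
    assign(w, s, envir = .pt_cache)
  }
  stems_u <- vapply(uniq, function(w) get(w, envir = .pt_cache, inherits = FALSE),
                    character(1), USE.NAMES = FALSE)
  stems_u[match(words, uniq)]
}
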
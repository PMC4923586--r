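# Tokenization, stop-word flagging, stemming, coarse POS tagging.

.dt_env <- new.env(parent = emptyenv())

#' Bundled English stop-word list
#'
#' Reads the editable stop-word file shipped under `extdata` (one word per
#' line, `#` comments allowed), or a user-supplied file in the same format.
#'
#' @param path optional path to an alternative stop-word file.
#' @return character vector of lowercase stop words.
#' @export
stopword_list <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.dt_env$stopwords)) return(.dt_env$stopwords)
    path <- system.file("extdata", "stopwords.txt", package = "demotext")
    sw <- .read_word_file(path)
    .dt_env$stopwords <- sw
    return(sw)
  }
  .read_word_file(path)
}

.read_word_file <- function(path) {
  stopifnot(file.exists(path))
  x <- readLines(path, warn = FALSE, encoding = "UTF-8")
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(stringi::stri_trans_tolower(x))
}

# Extract lowercase tokens from one or more texts.  Hashtags are kept whole
# (with '#'); alphanumeric runs (drug names like "b12") and apostrophes are
# kept; other symbols (emoji etc.) become their own tokens.
.tokenize_vec <- function(texts) {
  texts <- stringi::stri_trans_tolower(texts)
  stringi::stri_extract_all_regex(
    texts, "#[\\p{L}\\p{N}_]+|[\\p{L}\\p{N}]+(?:'[\\p{L}]+)?|[\\p{So}\\p{Sk}]",
    omit_no_match = TRUE
  )
}

#' Normalize a text into a token sequence
#'
#' Splits on whitespace/punctuation keeping hashtags and alphanumeric tokens
#' intact, flags stop words (they are kept, downstream stages decide what to
#' drop), and attaches a Porter stem to every token. Hashtags and non-letter
#' tokens are exempt from stemming (their stem equals their surface form).
#'
#' @param text a single character string.
#' @return a tibble with columns `surface`, `stem`, `is_stopword` and `pos`
#'   (`NA` until [pos_tag()] is applied), one row per token in order.
#' @examples
#' normalize_text("Headaches and migraines")
#' @export
normalize_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- .tokenize_vec(text)[[1]]
  tibble::tibble(
    surface = toks,
    stem = porter_stem(toks),
    is_stopword = toks %in% stopword_list(),
    pos = rep(NA_character_, length(toks))
  )
}

# Vectorized corpus tokenizer: one data.table of tokens for many posts.
# Internal hot path shared by scoring, annotation and distinctive analysis.
.tokenize_corpus <- function(texts, ids) {
  tl <- .tokenize_vec(texts)
  n <- lengths(tl)
  toks <- unlist(tl, use.names = FALSE)
  if (is.null(toks)) toks <- character(0)
  dt <- data.table::data.table(
    post_id = rep(ids, n),
    idx = sequence(n),
    surface = toks
  )
  dt[, stem := porter_stem(surface)]
  dt[, is_stopword := surface %chin% stopword_list()]
  dt[]
}

# small closed-class seed lists for the rule tagger
.tag_adj <- c("good", "bad", "great", "terrible", "happy", "sad", "sick",
              "healthy", "chronic", "severe", "mild", "high", "low", "new",
              "old", "strong", "weak", "awful", "nice", "worse", "better")
.tag_verb <- c("is", "am", "are", "was", "were", "be", "been", "have", "has",
               "had", "do", "does", "did", "take", "took", "taking", "feel",
               "felt", "get", "got", "go", "went", "hurt", "hurts", "love",
               "hate", "need", "want", "think", "know", "help")
.tag_adv <- c("very", "really", "quite", "too", "so", "always", "never",
              "often", "again", "well", "badly")

#' Coarse part-of-speech tagging
#'
#' Fills the `pos` column of a normalized token sequence with one of
#' `noun`, `verb`, `adj`, `adv`, `other`, using a bundled rule/suffix tagger:
#' small closed-class seed lists, then suffix rules (`-ly` adverb, adjectival
#' `-ous/-ful/-ive/-able/-ible/-al/-ic/-ish/-less`, verbal `-ing/-ed/-ize/-ise`),
#' nominal `-ness/-tion/-sion/-ment/-ity/-er/-ism`; anything unrecognized —
#' including stop words, hashtags, numbers and symbols — is tagged `other`,
#' which downstream lexicon lookup treats as "no POS information" and falls
#' back to POS-insensitive matching.
#'
#' Any external tagger can replace this one via `tagger`: a function taking a
#' character vector of surfaces and returning a same-length character vector
#' of coarse tags.
#'
#' @param tokens a token tibble from [normalize_text()].
#' @param tagger optional replacement tagging function.
#' @return `tokens` with `pos` filled.
#' @export
pos_tag <- function(tokens, tagger = NULL) {
  if (is.null(tagger)) tagger <- coarse_tagger
  tokens$pos <- tagger(tokens$surface)
  stopifnot(length(tokens$pos) == nrow(tokens))
  tokens
}

#' Default rule/suffix tagger
#'
#' @param surfaces character vector of token surfaces.
#' @return character vector of coarse tags, same length.
#' @export
coarse_tagger <- function(surfaces) {
  s <- stringi::stri_trans_tolower(surfaces)
  pos <- rep("other", length(s))
  alpha <- grepl("^[a-z]+$", s)
  sw <- s %in% stopword_list()
  pos[alpha & s %in% .tag_adj] <- "adj"
  pos[alpha & s %in% .tag_verb] <- "verb"
  pos[alpha & s %in% .tag_adv] <- "adv"
  un <- alpha & pos == "other" & !sw
  pos[un & grepl("ly$", s)] <- "adv"
  un <- alpha & pos == "other" & !sw
  pos[un & grepl("(ous|ful|ive|able|ible|ish|less|al|ic)$", s) & nchar(s) > 4] <- "adj"
  un <- alpha & pos == "other" & !sw
  pos[un & grepl("(ing|ed|ize|ise)$", s) & nchar(s) > 4] <- "verb"
  un <- alpha & pos == "other" & !sw
  pos[un & grepl("(ness|tion|sion|ment|ity|ism)$", s) & nchar(s) > 4] <- "noun"
  # anything else stays "other": the scorer then uses POS-insensitive lookup,
  # which is the right degradation for out-of-vocabulary health terms
  pos
}
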
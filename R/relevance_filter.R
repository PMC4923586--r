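# Health-keyword relevance filter for general social-network posts.

.keyword_categories <- c("drug", "hashtag", "disorder", "pharma", "insurance")

#' Load a health-keyword list
#'
#' TSV dialect `phrase<TAB>category`; phrases are lowercased, must be unique,
#' hashtag entries must start with `#`. A 40-entry fixture ships under
#' `extdata/keywords.tsv`; a full keyword list in the same layout drops in
#' unchanged.
#'
#' @param path keyword file, default the bundled fixture.
#' @return tibble with `phrase`, `category`.
#' @export
load_keyword_list <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "keywords.tsv", package = "demotext")
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("phrase", "category"))
  dt[, phrase := stringi::stri_trans_tolower(phrase)]
  if (anyDuplicated(dt$phrase)) stop("duplicate keyword phrases")
  stopifnot(all(dt$category %in% .keyword_categories))
  ht <- dt$category == "hashtag"
  if (any(ht & !startsWith(dt$phrase, "#")))
    stop("hashtag keywords must start with '#'")
  tibble::as_tibble(dt)
}

# token sequences for each keyword phrase (multiword keywords are matched as
# adjacent surface tokens, before stemming)
.keyword_tokens <- function(keywords) {
  lapply(stringi::stri_split_regex(keywords$phrase, "\\s+"), tolower)
}

#' Is a post health-relevant?
#'
#' A post is relevant iff at least one keyword phrase occurs in it,
#' case-insensitively, on token boundaries: "aids" never matches inside
#' "said", hashtag keywords match whole `#...` tokens, and multiword
#' keywords must appear as adjacent tokens. Matching is on surface tokens
#' (keywords are surface forms like drug names), before any stemming.
#'
#' @param text post text (single string).
#' @param keywords tibble from [load_keyword_list()].
#' @return list `relevant` (logical) and `matched` (character vector of
#'   matched keyword phrases).
#' @export
is_relevant <- function(text, keywords) {
  stopifnot(nrow(keywords) > 0L)
  toks <- .tokenize_vec(text)[[1]]
  matched <- character(0)
  if (length(toks) > 0L) {
    kw <- .keyword_tokens(keywords)
    for (i in seq_along(kw)) {
      k <- kw[[i]]
      if (length(k) == 1L) {
        if (k %in% toks) matched <- c(matched, keywords$phrase[i])
      } else {
        starts <- which(toks == k[1])
        for (s in starts) {
          if (s + length(k) - 1L <= length(toks) &&
              all(toks[s:(s + length(k) - 1L)] == k)) {
            matched <- c(matched, keywords$phrase[i]); break
          }
        }
      }
    }
  }
  list(relevant = length(matched) > 0L, matched = matched)
}

#' Filter a corpus down to health-relevant posts
#'
#' Only posts from `social_network` sources are subject to the keyword
#' filter (drug-review and forum posts are health-related by construction
#' and pass through). Returns the kept posts and per-keyword match counts
#' (number of kept social-network posts matching each keyword).
#'
#' @param posts post tibble.
#' @param keywords tibble from [load_keyword_list()].
#' @return list `kept` (post tibble) and `counts` (tibble `phrase`,
#'   `n_posts`).
#' @export
filter_corpus <- function(posts, keywords) {
  stopifnot(nrow(keywords) > 0L)
  social <- posts$source == "social_network"
  counts <- stats::setNames(integer(nrow(keywords)), keywords$phrase)
  keep <- !social
  if (any(social)) {
    tl <- .tokenize_vec(posts$text[social])
    kw <- .keyword_tokens(keywords)
    hit <- logical(sum(social))
    for (i in seq_along(kw)) {
      k <- kw[[i]]
      if (length(k) == 1L) {
        h <- vapply(tl, function(t) k %in% t, logical(1))
      } else {
        h <- vapply(tl, function(t) {
          n <- length(t)
          if (n < length(k)) return(FALSE)
          for (s in which(t == k[1])) {
            if (s + length(k) - 1L <= n && all(t[s:(s + length(k) - 1L)] == k))
              return(TRUE)
          }
          FALSE
        }, logical(1))
      }
      counts[i] <- sum(h)
      hit <- hit | h
    }
    keep[social] <- hit
  }
  kept <- posts[keep, , drop = FALSE]
  if (nrow(kept) == 0L) warning("relevance filter removed every post")
  list(kept = kept,
       counts = tibble::tibble(phrase = keywords$phrase,
                               n_posts = unname(counts)))
}
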
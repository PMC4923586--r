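# Sentiment / emotion lexicon loading, greedy longest-match phrase mapping,
# per-post scoring and per-group aggregation with group-vs-rest tests.

.emotions <- c("anger", "fear", "trust", "disgust", "anticipation",
               "surprise", "joy", "sadness")
.coarse_pos <- c("noun", "verb", "adj", "adv", "any")

.swn_pos_map <- c(n = "noun", v = "verb", a = "adj", s = "adj", r = "adv",
                  noun = "noun", verb = "verb", adj = "adj", adv = "adv",
                  any = "any")

# Normalize a lexicon phrase the same way posts are normalized: lowercase,
# split multiword forms ('_' or space), Porter-stem each word.
.phrase_key <- function(phrases) {
  words <- stringi::stri_split_regex(stringi::stri_trans_tolower(phrases), "[_\\s]+")
  vapply(words, function(w) paste(porter_stem(w[nzchar(w)]), collapse = " "),
         character(1))
}

#' Load a SentiWordNet-style sentiment lexicon
#'
#' Accepts either the public SentiWordNet 3.0 layout
#' (`POS<TAB>ID<TAB>PosScore<TAB>NegScore<TAB>SynsetTerms<TAB>Gloss`, terms
#' carrying `#rank` suffixes) or the compact dialect
#' `POS<TAB>term(s)<TAB>PosScore<TAB>NegScore`; `#` lines are comments in
#' both. The objective score is derived as `1 - pos - neg`, entries are
#' stemmed with the same pipeline as posts, and multiple senses of the same
#' (stems, POS) pair are collapsed by unweighted averaging.
#'
#' @param path lexicon file.
#' @return a lexicon index usable by [match_phrases()]; its `$entries` tibble
#'   has columns `stems`, `n_words`, `pos`, `positive`, `negative`,
#'   `objective`, each triple summing to 1 within 1e-6.
#' @export
load_sentiment_lexicon <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) stop("empty sentiment lexicon: ", path)
  rows <- strsplit(lines, "\t", fixed = TRUE)
  out <- vector("list", length(rows))
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) >= 5 && !is.na(suppressWarnings(as.numeric(f[3]))) &&
        grepl("^[0-9]+$", f[2])) {
      # public layout: POS ID PosScore NegScore SynsetTerms Gloss
      pos <- f[1]; p <- as.numeric(f[3]); n <- as.numeric(f[4])
      terms <- strsplit(f[5], " ", fixed = TRUE)[[1]]
      terms <- sub("#[0-9]+$", "", terms)
    } else if (length(f) >= 4) {
      pos <- f[1]; p <- as.numeric(f[3]); n <- as.numeric(f[4])
      terms <- strsplit(f[2], " ", fixed = TRUE)[[1]]
    } else stop("unparseable sentiment lexicon row ", i)
    if (is.na(p) || is.na(n)) stop("non-numeric scores at sentiment row ", i)
    o <- 1 - p - n
    if (o < -1e-6 || p < -1e-6 || n < -1e-6)
      stop("sentiment scores at row ", i, " violate pos+neg+obj = 1")
    cp <- .swn_pos_map[tolower(pos)]
    if (is.na(cp)) cp <- "any"
    out[[i]] <- data.table::data.table(
      stems = .phrase_key(terms), pos = cp, positive = p, negative = n,
      objective = max(o, 0))
  }
  dt <- data.table::rbindlist(out)
  dt <- dt[nzchar(stems)]
  dt <- dt[, .(positive = mean(positive), negative = mean(negative),
               objective = mean(objective)), by = .(stems, pos)]
  bad <- abs(dt$positive + dt$negative + dt$objective - 1) > 1e-6
  if (any(bad)) stop("sentiment entries violating sum-to-one after averaging: ",
                     paste(utils::head(dt$stems[bad], 3), collapse = ", "))
  .build_lexicon_index(dt)
}

#' Load an NRC-style word-emotion lexicon
#'
#' Dialect: `word<TAB>emotion<TAB>0/1`, the layout of the public EmoLex file;
#' `positive`/`negative` association rows are ignored, the eight basic
#' emotions are kept. Words are stemmed; a stem carries an emotion if any
#' surface form mapping to it does.
#'
#' @param path lexicon file.
#' @return tibble with `stems` plus one logical column per emotion.
#' @export
load_emotion_lexicon <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("word", "emotion", "flag"))
  if (nrow(dt) == 0L) stop("empty emotion lexicon: ", path)
  dt <- dt[emotion %in% .emotions & flag == 1]
  dt[, stems := .phrase_key(word)]
  wide <- data.table::dcast(dt, stems ~ emotion, fun.aggregate = length)
  for (e in .emotions) {
    if (!e %in% names(wide)) wide[, (e) := 0L]
    wide[, (e) := get(e) > 0L]
  }
  tibble::as_tibble(wide[, c("stems", .emotions), with = FALSE])
}

# Shared index for greedy matching: entries keyed by stems string, split by
# first stem, with max phrase length.
.build_lexicon_index <- function(entries) {
  entries <- data.table::as.data.table(entries)
  entries[, n_words := stringi::stri_count_fixed(stems, " ") + 1L]
  entries[, first := stringi::stri_extract_first_regex(stems, "^[^ ]+")]
  entries[, entry_id := .I]
  idx <- split(seq_len(nrow(entries)), entries$first)
  structure(list(entries = entries, by_first = idx,
                 max_len = max(entries$n_words)),
            class = "demotext_lexicon")
}

#' @export
print.demotext_lexicon <- function(x, ...) {
  cat("<lexicon index>", nrow(x$entries), "entries, max phrase length",
      x$max_len, "\n")
  invisible(x)
}

# POS compatibility: untagged / 'other' tokens match POS-insensitively;
# otherwise the entry must be POS-agnostic or agree with the token.
.pos_ok <- function(entry_pos, token_pos) {
  if (is.na(token_pos) || token_pos == "other") return(rep(TRUE, length(entry_pos)))
  entry_pos == "any" | entry_pos == token_pos
}

#' Greedy longest-match phrase mapping
#'
#' Scans the token sequence left to right; at each position the longest
#' lexicon phrase starting there is matched and the cursor advances past it,
#' so a two-word entry like "heart attack" always wins over its one-word
#' prefix. At equal length, an entry whose POS agrees with the token's tag is
#' preferred over a POS-agnostic one. Stop-word tokens can participate inside
#' multiword phrases but are not matched as single-word phrases.
#'
#' @param tokens token tibble from [normalize_text()] (optionally POS-tagged).
#' @param lexicon index from [load_sentiment_lexicon()] or
#'   [concept_dictionary_index()].
#' @return tibble with `start`, `length`, `entry_id`, `stems` for each match.
#' @export
match_phrases <- function(tokens, lexicon) {
  stopifnot(inherits(lexicon, "demotext_lexicon"))
  stems <- tokens$stem
  pos <- if ("pos" %in% names(tokens)) tokens$pos else rep(NA_character_, length(stems))
  is_sw <- if ("is_stopword" %in% names(tokens)) tokens$is_stopword else
    rep(FALSE, length(stems))
  n <- length(stems)
  ent <- lexicon$entries
  res_start <- integer(0); res_len <- integer(0); res_id <- integer(0)
  i <- 1L
  while (i <= n) {
    cand <- lexicon$by_first[[stems[i]]]
    hit <- 0L; hit_len <- 0L
    if (!is.null(cand)) {
      for (len in seq.int(min(lexicon$max_len, n - i + 1L), 1L)) {
        if (len == 1L && is_sw[i]) next
        sub <- cand[ent$n_words[cand] == len]
        if (length(sub) == 0L) next
        key <- paste(stems[i:(i + len - 1L)], collapse = " ")
        sub <- sub[ent$stems[sub] == key]
        if (length(sub) == 0L) next
        ok <- sub[.pos_ok(ent$pos[sub], pos[i])]
        if (length(ok) == 0L) next
        exact <- ok[ent$pos[ok] == pos[i] & !is.na(pos[i])]
        hit <- if (length(exact) > 0L) exact[1L] else ok[1L]
        hit_len <- len
        break
      }
    }
    if (hit > 0L) {
      res_start <- c(res_start, i); res_len <- c(res_len, hit_len)
      res_id <- c(res_id, hit)
      i <- i + hit_len
    } else i <- i + 1L
  }
  tibble::tibble(start = res_start, length = res_len, entry_id = res_id,
                 stems = ent$stems[res_id])
}

#' Score one post for sentiment and emotion
#'
#' Sentiment is the unweighted mean of the (positive, negative, objective)
#' triples of all greedily matched lexicon phrases; a post with no sentiment
#' match is returned unscored (`n_matched = 0`, `NA` triple) and is excluded
#' from group denominators downstream. Emotion flag *e* is set iff at least
#' one token stem carries *e* in the emotion lexicon.
#'
#' @param text post text.
#' @param sentiment_lexicon index from [load_sentiment_lexicon()].
#' @param emotion_lexicon tibble from [load_emotion_lexicon()].
#' @return one-row tibble: `n_matched`, `positive`, `negative`, `objective`,
#'   and one logical column per emotion.
#' @export
score_post <- function(text, sentiment_lexicon = NULL, emotion_lexicon = NULL) {
  toks <- pos_tag(normalize_text(text))
  out <- tibble::tibble(n_matched = 0L, positive = NA_real_,
                        negative = NA_real_, objective = NA_real_)
  if (!is.null(sentiment_lexicon)) {
    m <- match_phrases(toks, sentiment_lexicon)
    if (nrow(m) > 0L) {
      e <- sentiment_lexicon$entries[m$entry_id]
      out$n_matched <- nrow(m)
      out$positive <- mean(e$positive)
      out$negative <- mean(e$negative)
      out$objective <- mean(e$objective)
    }
  }
  for (em in .emotions) out[[em]] <- FALSE
  if (!is.null(emotion_lexicon)) {
    hit <- emotion_lexicon[emotion_lexicon$stems %in% toks$stem, , drop = FALSE]
    if (nrow(hit) > 0L)
      for (em in .emotions) out[[em]] <- any(hit[[em]])
  }
  out
}

#' Score every post in a corpus
#'
#' Vectorized equivalent of [score_post()] applied to each post. When every
#' sentiment entry is a single word the matcher reduces to a per-token lookup
#' and is fully vectorized; multiword lexicons fall back to the per-post
#' greedy scan.
#'
#' @param posts post tibble.
#' @param sentiment_lexicon,emotion_lexicon as in [score_post()] (either may
#'   be `NULL` to skip that component).
#' @return tibble keyed by `post_id` with the same columns as [score_post()].
#' @export
score_posts <- function(posts, sentiment_lexicon = NULL, emotion_lexicon = NULL) {
  dt <- .tokenize_corpus(posts$text, posts$post_id)
  res <- data.table::data.table(post_id = posts$post_id, n_matched = 0L,
                                positive = NA_real_, negative = NA_real_,
                                objective = NA_real_)
  if (!is.null(sentiment_lexicon)) {
    ent <- sentiment_lexicon$entries
    if (sentiment_lexicon$max_len == 1L) {
      dt[, pos := coarse_tagger(surface)]
      sub <- dt[!is_stopword]
      m <- merge(sub, ent[, .(stems, entry_pos = pos, positive, negative,
                              objective, entry_id)],
                 by.x = "stem", by.y = "stems", allow.cartesian = TRUE)
      m <- m[is.na(pos) | pos == "other" | entry_pos == "any" | entry_pos == pos]
      m[, pref := as.integer(!is.na(pos) & pos != "other" & entry_pos == pos)]
      data.table::setorder(m, post_id, idx, -pref, entry_id)
      m <- m[, utils::head(.SD, 1L), by = .(post_id, idx)]
      agg <- m[, .(n_matched = .N, positive = mean(positive),
                   negative = mean(negative), objective = mean(objective)),
               by = post_id]
    } else {
      toks_by_post <- split(dt, by = "post_id", sorted = FALSE)
      agg_l <- lapply(toks_by_post, function(td) {
        td[, pos := coarse_tagger(surface)]
        m <- match_phrases(td, sentiment_lexicon)
        if (nrow(m) == 0L) return(NULL)
        e <- ent[m$entry_id]
        data.table::data.table(post_id = td$post_id[1L], n_matched = nrow(m),
                               positive = mean(e$positive),
                               negative = mean(e$negative),
                               objective = mean(e$objective))
      })
      agg <- data.table::rbindlist(agg_l)
    }
    if (!is.null(agg) && nrow(agg) > 0L) {
      idx <- match(agg$post_id, res$post_id)
      res$n_matched[idx] <- agg$n_matched
      res$positive[idx] <- agg$positive
      res$negative[idx] <- agg$negative
      res$objective[idx] <- agg$objective
    }
  }
  for (em in .emotions) res[, (em) := FALSE]
  if (!is.null(emotion_lexicon)) {
    el <- data.table::as.data.table(emotion_lexicon)
    m <- merge(dt[, .(post_id, stem)], el, by.x = "stem", by.y = "stems")
    if (nrow(m) > 0L) {
      agg <- m[, lapply(.SD, any), by = post_id, .SDcols = .emotions]
      idx <- match(agg$post_id, res$post_id)
      for (em in .emotions) res[[em]][idx] <- agg[[em]]
    }
  }
  tibble::as_tibble(res)
}

# group-vs-rest two-proportion z-test (chi-square form, no continuity
# correction); degenerate pooled proportions give p = 1
.prop_test_p <- function(x1, n1, x2, n2) {
  if (n1 == 0L || n2 == 0L) return(NA_real_)
  pool <- (x1 + x2) / (n1 + n2)
  if (pool <= 0 || pool >= 1) return(1)
  # chi-square small-count warnings are expected at tiny group sizes
  suppressWarnings(
    stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE)$p.value)
}

#' Aggregate post scores by demographic group
#'
#' For each value of the chosen attribute: mean sentiment triple over scored
#' posts (posts with at least one sentiment match), and per emotion the
#' percentage of posts flagged with it, with a two-sided two-proportion
#' z-test of the group against the union of all other groups. Sentiment
#' means are likewise tested group-vs-rest with Welch's t-test. The emotion
#' denominator is the group's scored posts when a sentiment lexicon was
#' applied, otherwise all posts in the group.
#'
#' @param scores tibble from [score_posts()].
#' @param posts,users corpus tibbles.
#' @param attribute partition attribute, see [partition_posts()].
#' @param alpha significance level for the `significant` flags.
#' @return list of tibbles `sentiment` (one row per group) and `emotions`
#'   (one row per group x emotion). The emotion table carries the raw
#'   `p_value` driving the `significant` flag plus a Benjamini-Hochberg
#'   adjusted `p_value_bh` column as a clearly-separated extension.
#' @export
aggregate_groups <- function(scores, posts, users, attribute, alpha = 0.05) {
  parts <- partition_posts(posts, users, attribute)
  if (length(parts) == 0L) stop("no groups for attribute '", attribute, "'")
  sc <- data.table::as.data.table(scores)
  has_sent <- any(sc$n_matched > 0L)
  per_group <- lapply(names(parts), function(g) {
    ids <- parts[[g]]$post_id
    s <- sc[post_id %in% ids]
    if (has_sent) s_den <- s[n_matched > 0L] else s_den <- s
    list(group = g, n_posts = nrow(s), scored = s_den)
  })
  names(per_group) <- names(parts)

  sent_rows <- list(); emo_rows <- list()
  for (g in names(per_group)) {
    grp <- per_group[[g]]$scored
    rest <- data.table::rbindlist(lapply(setdiff(names(per_group), g),
                                         function(h) per_group[[h]]$scored))
    if (nrow(grp) == 0L) {
      warning("group '", g, "' has no scored posts; omitted")
      next
    }
    p_pos <- p_neg <- NA_real_
    if (has_sent && nrow(rest) > 1L && nrow(grp) > 1L) {
      p_pos <- tryCatch(stats::t.test(grp$positive, rest$positive)$p.value,
                        error = function(e) NA_real_)
      p_neg <- tryCatch(stats::t.test(grp$negative, rest$negative)$p.value,
                        error = function(e) NA_real_)
    }
    sent_rows[[g]] <- tibble::tibble(
      group = g, n_posts = per_group[[g]]$n_posts, n_scored = nrow(grp),
      positive = if (has_sent) mean(grp$positive) else NA_real_,
      negative = if (has_sent) mean(grp$negative) else NA_real_,
      objective = if (has_sent) mean(grp$objective) else NA_real_,
      p_positive = p_pos, p_negative = p_neg)
    for (em in .emotions) {
      x1 <- sum(grp[[em]]); n1 <- nrow(grp)
      x2 <- sum(rest[[em]]); n2 <- nrow(rest)
      pv <- .prop_test_p(x1, n1, x2, n2)
      emo_rows[[paste(g, em)]] <- tibble::tibble(
        group = g, emotion = em, n_posts = n1,
        percentage = 100 * x1 / n1, p_value = pv,
        significant = !is.na(pv) & pv <= alpha)
    }
  }
  emotions <- do.call(rbind, unname(emo_rows))
  if (!is.null(emotions)) {
    # extension column only: the significance flag follows the raw p-value
    emotions$p_value_bh <- stats::p.adjust(emotions$p_value, method = "BH")
  }
  list(sentiment = do.call(rbind, sent_rows), emotions = emotions)
}
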
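sent_lex <- load_sentiment_lexicon(extdata("sentiment.tsv"))
emo_lex <- load_emotion_lexicon(extdata("emotions.tsv"))

test_that("sentiment loader derives the objective score and enforces sum-to-one", {
  e <- sent_lex$entries
  expect_true(all(abs(e$positive + e$negative + e$objective - 1) < 1e-6))
  # pos=0.75, neg=0 -> objective 0.25
  w <- e[e$stems == porter_stem("wonderful")]
  expect_equal(w$objective, 0.25)

  # duplicate senses of one (term, POS) are averaged into a single entry
  f <- write_temp_lexicon(c("a\tgood\t0.5\t0", "a\tgood\t0.75\t0.25",
                            "n\tgood\t0.25\t0"))
  lx <- load_sentiment_lexicon(f)
  g <- lx$entries[lx$entries$stems == "good"]
  expect_equal(nrow(g), 2L)                       # one per POS
  expect_equal(g$positive[g$pos == "adj"], 0.625) # mean(.5, .75)
  expect_equal(g$negative[g$pos == "adj"], 0.125)

  expect_error(load_sentiment_lexicon(write_temp_lexicon("# only a comment")),
               "empty")
  expect_error(load_sentiment_lexicon(write_temp_lexicon("a\tbad\t0.9\t0.9")),
               "violate")
})

test_that("the public SentiWordNet layout parses identically", {
  f <- write_temp_lexicon(c(
    "# SentiWordNet v3.0",
    "a\t00001740\t0.125\t0\table#1\tcapable of",
    "n\t00002098\t0\t0.625\theadache#1 cephalalgia#2\ta pain in the head"))
  lx <- load_sentiment_lexicon(f)
  expect_true("headach" %in% lx$entries$stems)
  expect_equal(lx$entries$negative[lx$entries$stems == "headach"], 0.625)
})

test_that("greedy matcher takes the longest phrase and prefers POS-exact entries", {
  toks <- pos_tag(normalize_text("heart attack hurt"))
  m <- match_phrases(toks, sent_lex)
  expect_equal(m$stems[1], "heart attack")
  expect_false("heart" %in% m$stems)
  expect_true("hurt" %in% m$stems)

  # POS-specific entry beats the POS-agnostic one at equal length
  f <- write_temp_lexicon(c("a\tgood\t0.8\t0", "any\tgood\t0.2\t0"))
  lx <- load_sentiment_lexicon(f)
  toks <- pos_tag(normalize_text("good"))
  m <- match_phrases(toks, lx)
  e <- lx$entries[m$entry_id]
  expect_equal(e$positive, 0.8)

  # no overlap -> no matches
  expect_equal(nrow(match_phrases(normalize_text("bkg0001 bkg0002"), sent_lex)), 0L)
})

test_that("greedy matcher equals the exhaustive maximal-match oracle on random strings", {
  f <- write_temp_lexicon(c(
    "n\theart_attack\t0.1\t0.2", "n\theart\t0\t0.1", "n\tattack\t0\t0.3",
    "n\theart_attack_scare\t0\t0.5", "n\tpain\t0\t0.4", "n\tchest_pain\t0\t0.5"))
  lx <- load_sentiment_lexicon(f)
  vocab <- c("heart", "attack", "scare", "pain", "chest", "filler1", "filler2")
  set.seed(42)
  for (i in 1:200) {
    stems <- sample(vocab, sample(3:10, 1), replace = TRUE)
    toks <- tibble::tibble(surface = stems, stem = stems,
                           is_stopword = FALSE, pos = NA_character_)
    mine <- match_phrases(toks, lx)
    orac <- oracle_match(stems, lx$entries)
    if (is.null(orac)) {
      expect_equal(nrow(mine), 0L)
    } else {
      expect_equal(mine$start, orac$start)
      expect_equal(mine$length, orac$length)
      expect_equal(mine$stems, orac$stems)
    }
  }
})

test_that("post scores are phrase means; zero-match posts stay unscored", {
  # matched entries (.75,0,.25) and (0,.625,.375) -> mean (.375,.3125,.3125)
  s <- score_post("wonderful unbearable", sent_lex, emo_lex)
  expect_equal(s$n_matched, 2L)
  expect_equal(c(s$positive, s$negative, s$objective), c(0.375, 0.3125, 0.3125))

  one <- score_post("wonderful", sent_lex, emo_lex)
  expect_equal(c(one$positive, one$negative, one$objective), c(0.75, 0, 0.25))

  z <- score_post("bkg0001 bkg0002", sent_lex, emo_lex)
  expect_equal(z$n_matched, 0L)
  expect_true(is.na(z$positive))

  flag <- score_post("feeling furious today", sent_lex, emo_lex)
  expect_true(flag$anger)
  expect_false(flag$joy)
})

test_that("vectorized corpus scoring agrees with per-post scoring", {
  cfg <- generator_config(seed = 21, posts_per_group = 40L)
  corp <- generate_corpus(cfg)
  fast <- score_posts(corp$posts, sent_lex, emo_lex)
  slow <- do.call(rbind, lapply(corp$posts$text, score_post,
                                sentiment_lexicon = sent_lex,
                                emotion_lexicon = emo_lex))
  expect_equal(fast$n_matched, slow$n_matched)
  expect_equal(fast$positive, slow$positive)
  expect_equal(fast$negative, slow$negative)
  for (e in c("anger", "fear", "trust", "joy"))
    expect_equal(fast[[e]], slow[[e]])
  # triples of scored posts sum to 1
  sc <- fast[fast$n_matched > 0, ]
  expect_true(all(abs(sc$positive + sc$negative + sc$objective - 1) < 1e-6))
})

test_that("scoring a post is independent of corpus order", {
  cfg <- generator_config(seed = 22, posts_per_group = 30L)
  corp <- generate_corpus(cfg)
  a <- score_posts(corp$posts, sent_lex, emo_lex)
  perm <- sample(nrow(corp$posts))
  b <- score_posts(corp$posts[perm, ], sent_lex, emo_lex)
  b <- b[match(a$post_id, b$post_id), ]
  expect_equal(a$positive, b$positive)
  expect_equal(a$anger, b$anger)
})

test_that("group aggregation: means, percentages, and group-vs-rest tests", {
  posts <- posts_tibble(sprintf("p%d", 1:4), c("u1", "u2", "u3", "u4"),
                        c("wonderful", "unbearable", "furious awful", "relief"),
                        source = "forum")
  users <- users_tibble(sprintf("u%d", 1:4),
                        gender = c("female", "female", "male", "male"))
  sc <- score_posts(posts, sent_lex, emo_lex)
  agg <- aggregate_groups(sc, posts, users, "gender")
  fem <- agg$sentiment[agg$sentiment$group == "female", ]
  expect_equal(fem$positive, mean(c(0.75, 0)))
  # group triple still sums to one
  expect_true(all(abs(agg$sentiment$positive + agg$sentiment$negative +
                        agg$sentiment$objective - 1) < 1e-6))
  ang <- agg$emotions[agg$emotions$emotion == "anger", ]
  expect_equal(ang$percentage[ang$group == "male"], 100 * 1 / 2)
  expect_equal(ang$percentage[ang$group == "female"], 0)
  expect_true(all(agg$emotions$percentage >= 0 & agg$emotions$percentage <= 100))
})
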
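# Monte-Carlo checks of the group-vs-rest emotion test: type-I error under a
# null generator and power under a configured injection contrast.

.emotion_only_config <- function(seed, posts_per_group, injection_by_group) {
  generator_config(
    seed = seed,
    posts_per_group = posts_per_group,
    post_length_mean = 10,
    background_vocab_size = 100L,
    planted_terms = default_planted_terms(c("male", "female"), n_terms = 0L),
    sentiment_injection = list(male = c(positive = 0, negative = 0),
                               female = c(positive = 0, negative = 0)),
    emotion_injection = injection_by_group
  )
}

#' Null rejection rate of the emotion comparison
#'
#' Generates corpora where both groups share identical emotion-injection
#' probabilities, scores them with the bundled emotion lexicon, runs every
#' group-vs-rest emotion comparison, and returns the fraction flagged at
#' `alpha` — which should sit near `alpha` for a calibrated test.
#'
#' @param n_replicates number of independent corpora.
#' @param posts_per_group posts per group in each corpus.
#' @param p common per-post emotion-injection probability.
#' @param alpha significance level.
#' @param seed base seed; replicate r uses `seed + r`.
#' @return list `rejection_rate`, `n_comparisons`.
#' @export
simulate_null_rejection_rate <- function(n_replicates = 1000L,
                                         posts_per_group = 500L,
                                         p = 0.3, alpha = 0.05, seed = 1L) {
  emo_lex <- load_emotion_lexicon(
    system.file("extdata", "emotions.tsv", package = "demotext"))
  inj <- stats::setNames(rep(p, length(.emotions)), .emotions)
  n_rej <- 0L; n_cmp <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- .emotion_only_config(seed + r, posts_per_group,
                                list(male = inj, female = inj))
    corp <- generate_corpus(cfg)
    sc <- score_posts(corp$posts, NULL, emo_lex)
    agg <- aggregate_groups(sc, corp$posts, corp$users, "gender", alpha = alpha)
    pv <- agg$emotions$p_value
    n_rej <- n_rej + sum(!is.na(pv) & pv <= alpha)
    n_cmp <- n_cmp + sum(!is.na(pv))
  }
  list(rejection_rate = n_rej / n_cmp, n_comparisons = n_cmp)
}

#' Power of the emotion comparison under an injection contrast
#'
#' One emotion is injected at `p_target` in the target group and `p_other`
#' elsewhere; all other emotions are injected at `p_other` everywhere.
#' Returns the fraction of replicates in which the target group's comparison
#' for that emotion is flagged significant.
#'
#' @param n_replicates replicates.
#' @param posts_per_group posts per group.
#' @param p_target,p_other per-post injection probabilities.
#' @param emotion the contrasted emotion.
#' @param alpha significance level.
#' @param seed base seed.
#' @return list `power`, `n_replicates`.
#' @export
simulate_power <- function(n_replicates = 200L, posts_per_group = 1000L,
                           p_target = 0.40, p_other = 0.25,
                           emotion = "anger", alpha = 0.05, seed = 1L) {
  emo_lex <- load_emotion_lexicon(
    system.file("extdata", "emotions.tsv", package = "demotext"))
  base <- stats::setNames(rep(p_other, length(.emotions)), .emotions)
  inj_t <- base; inj_t[[emotion]] <- p_target
  hits <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- .emotion_only_config(seed + r, posts_per_group,
                                list(male = inj_t, female = base))
    corp <- generate_corpus(cfg)
    sc <- score_posts(corp$posts, NULL, emo_lex)
    agg <- aggregate_groups(sc, corp$posts, corp$users, "gender", alpha = alpha)
    row <- agg$emotions[agg$emotions$group == "male" &
                          agg$emotions$emotion == emotion, ]
    if (nrow(row) == 1L && isTRUE(row$significant)) hits <- hits + 1L
  }
  list(power = hits / n_replicates, n_replicates = n_replicates)
}
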
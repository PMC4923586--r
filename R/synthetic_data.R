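# Synthetic corpus generator: known demographic structure, planted term
# enrichments with closed-form expected relative differences, injected
# sentiment/emotion lexicon words, configurable missingness.

# word pools shared between the generator and the fixture lexicons; pools are
# chosen so that their Porter stems do not collide with each other or with
# the stop-word list
.gen_pos_words <- c("wonderful", "excellent", "amazing", "relief", "helpful")
.gen_neg_words <- c("terrible", "awful", "painful", "horrible", "unbearable")
.gen_emotion_pools <- list(
  anger = c("furious", "rage", "irate"),
  fear = c("afraid", "terrified", "panic"),
  trust = c("reliable", "faithful", "dependable"),
  disgust = c("revolting", "nauseating", "repulsive"),
  anticipation = c("eager", "expectant", "awaiting"),
  surprise = c("astonished", "startled", "stunned"),
  joy = c("joyful", "delighted", "cheerful"),
  sadness = c("mournful", "gloomy", "sorrowful")
)

.region_states <- list(Northeast = c("NY", "MA", "PA"), Midwest = c("IL", "OH", "MN"),
                       South = c("TX", "FL", "GA"), West = c("CA", "WA", "AZ"))

#' Generator configuration
#'
#' Defines the study conditions a synthetic corpus emulates. Defaults match
#' the recovery setting used throughout the package's validation: two gender
#' groups, 5000 posts per group, 10 planted terms enriched 3:1
#' (per-token rates 0.03 in the target group vs 0.01 elsewhere), Poisson
#' post lengths with mean 20 tokens over a 50,000-word background vocabulary
#' (long-tailed enough that individual filler words sit below the occurrence
#' threshold at the default corpus size, as in real text), moderate
#' sentiment/emotion word injection, no missingness.
#'
#' @param seed integer; fixed seed gives byte-identical corpora.
#' @param attribute demographic attribute whose values define the groups
#'   (one of gender, age_group, ethnicity, region).
#' @param groups attribute values; each user is assigned one uniformly.
#' @param posts_per_group posts per group.
#' @param post_length_mean mean tokens per post (Poisson, min 1).
#' @param background_vocab_size number of neutral filler words.
#' @param planted_terms data frame with columns `term`, `target_group`,
#'   `rate_in_target`, `rate_elsewhere` (per-token probabilities).
#' @param sentiment_injection named list group -> c(positive=, negative=)
#'   per-token probabilities of emitting a positive / negative lexicon word.
#' @param emotion_injection named list group -> named vector (per emotion)
#'   of per-post probabilities of including one word of that emotion.
#' @param missingness probability a user's group attribute is withheld from
#'   their profile (the post still exists; the author is unannotated).
#' @param posts_per_user posts each user writes (1 = one user per post).
#' @param source source label of generated posts; the default `forum` marks
#'   them health-related by construction so the keyword relevance filter
#'   passes them through.
#' @return a `demotext_genconfig` list.
#' @export
generator_config <- function(seed,
                             attribute = "gender",
                             groups = c("male", "female"),
                             posts_per_group = 5000L,
                             post_length_mean = 20,
                             background_vocab_size = 50000L,
                             planted_terms = default_planted_terms(groups),
                             sentiment_injection = NULL,
                             emotion_injection = NULL,
                             missingness = 0,
                             posts_per_user = 1L,
                             source = "forum") {
  if (length(groups) < 1L) stop("need at least one group")
  if (posts_per_group < 1L) stop("need at least one post per group")
  stopifnot(attribute %in% c("gender", "age_group", "ethnicity", "region"))
  if (is.null(sentiment_injection))
    sentiment_injection <- stats::setNames(
      rep(list(c(positive = 0.05, negative = 0.05)), length(groups)), groups)
  if (is.null(emotion_injection))
    emotion_injection <- stats::setNames(
      rep(list(stats::setNames(rep(0.2, length(.emotions)), .emotions)),
          length(groups)), groups)
  pt <- tibble::as_tibble(planted_terms)
  if (nrow(pt) > 0L) {
    stopifnot(all(pt$target_group %in% groups),
              all(pt$rate_in_target >= 0 & pt$rate_in_target <= 1),
              all(pt$rate_elsewhere >= 0 & pt$rate_elsewhere <= 1),
              all(pt$rate_in_target >= pt$rate_elsewhere))
  }
  for (g in groups) {
    stopifnot(all(sentiment_injection[[g]] >= 0 & sentiment_injection[[g]] <= 1),
              all(emotion_injection[[g]] >= 0 & emotion_injection[[g]] <= 1))
  }
  stopifnot(missingness >= 0, missingness <= 1)
  structure(list(seed = as.integer(seed), attribute = attribute,
                 groups = groups, posts_per_group = as.integer(posts_per_group),
                 post_length_mean = post_length_mean,
                 background_vocab_size = as.integer(background_vocab_size),
                 planted_terms = pt,
                 sentiment_injection = sentiment_injection,
                 emotion_injection = emotion_injection,
                 missingness = missingness,
                 posts_per_user = as.integer(posts_per_user),
                 source = source),
            class = "demotext_genconfig")
}

#' Default planted-term design
#'
#' Ten terms, each enriched in one group at per-token rate 0.03 against 0.01
#' elsewhere (3:1), targets cycling over the groups. Term strings contain
#' digits so they are inert under stemming and cannot collide with real
#' vocabulary.
#'
#' @param groups group labels.
#' @param n_terms number of planted terms.
#' @param rate_in_target,rate_elsewhere per-token emission probabilities.
#' @return tibble with the four planted-term columns.
#' @export
default_planted_terms <- function(groups, n_terms = 10L,
                                  rate_in_target = 0.03,
                                  rate_elsewhere = 0.01) {
  tibble::tibble(
    term = sprintf("planted%02d", seq_len(n_terms)),
    target_group = rep_len(groups, n_terms),
    rate_in_target = rate_in_target,
    rate_elsewhere = rate_elsewhere
  )
}

# closed-form expected relative difference for configured rates
.expected_reldif <- function(rates) {
  m <- mean(rates)
  if (m == 0) return(rates * 0)
  (rates - m) / m
}

#' Generate a synthetic corpus
#'
#' Each post's tokens are drawn i.i.d. from its author's group-specific
#' multinomial over planted terms, sentiment words and background filler;
#' per post and emotion, one word of that emotion is appended with the
#' configured injection probability. The returned manifest carries the
#' closed-form expected relative difference of every planted term in every
#' group, `(r_g - mean_g r) / mean_g r`, and each group's expected emotion
#' percentages — the ground truth downstream stages are checked against.
#'
#' @param config a [generator_config()].
#' @return list `posts`, `users`, `manifest`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "demotext_genconfig"))
  set.seed(config$seed)
  groups <- config$groups
  n_g <- length(groups)
  npg <- config$posts_per_group
  n_posts <- n_g * npg
  pt <- config$planted_terms

  background <- sprintf("bkg%05d", seq_len(config$background_vocab_size))
  vocab <- c(pt$term, .gen_pos_words, .gen_neg_words, background)

  # per-group token distribution over vocab
  probs <- lapply(groups, function(g) {
    pr <- numeric(length(vocab))
    if (nrow(pt) > 0L)
      pr[seq_len(nrow(pt))] <- ifelse(pt$target_group == g,
                                      pt$rate_in_target, pt$rate_elsewhere)
    si <- config$sentiment_injection[[g]]
    np <- length(.gen_pos_words); nn <- length(.gen_neg_words)
    pr[nrow(pt) + seq_len(np)] <- si[["positive"]] / np
    pr[nrow(pt) + np + seq_len(nn)] <- si[["negative"]] / nn
    rem <- 1 - sum(pr)
    if (rem <= 0) stop("injection rates leave no probability for background")
    pr[nrow(pt) + np + nn + seq_along(background)] <- rem / length(background)
    pr
  })
  names(probs) <- groups

  group_of_post <- rep(groups, each = npg)
  lens <- pmax(1L, stats::rpois(n_posts, config$post_length_mean))
  texts <- character(n_posts)
  for (g in groups) {
    idx <- which(group_of_post == g)
    tok_total <- sum(lens[idx])
    draws <- sample(vocab, tok_total, replace = TRUE, prob = probs[[g]])
    splits <- rep(seq_along(idx), lens[idx])
    base <- vapply(split(draws, splits), paste, character(1), collapse = " ")
    suffix <- character(length(idx))
    ei <- config$emotion_injection[[g]]
    for (e in names(ei)) {
      if (ei[[e]] <= 0) next
      inject <- stats::runif(length(idx)) < ei[[e]]
      if (any(inject)) {
        w <- sample(.gen_emotion_pools[[e]], sum(inject), replace = TRUE)
        suffix[inject] <- paste0(suffix[inject], " ", w)
      }
    }
    texts[idx] <- paste0(base, suffix)
  }

  n_users <- ceiling(n_posts / config$posts_per_user)
  user_of_post <- rep(seq_len(n_users), each = config$posts_per_user)[seq_len(n_posts)]
  user_ids <- sprintf("u%06d", seq_len(n_users))
  # a user's group is the group of their posts (posts are laid out so that a
  # user's posts never straddle groups when posts_per_user divides npg)
  group_of_user <- group_of_post[match(seq_len(n_users), user_of_post)]
  withheld <- stats::runif(n_users) < config$missingness

  users <- users_tibble(user_id = user_ids)
  val <- ifelse(withheld, NA_character_, group_of_user)
  if (config$attribute == "gender") {
    users$gender <- val
    users$gender_provenance <- ifelse(is.na(val), "missing", "reported")
  } else if (config$attribute == "ethnicity") {
    users$ethnicity <- val
    users$ethnicity_provenance <- ifelse(is.na(val), "missing", "reported")
  } else if (config$attribute == "age_group") {
    lo <- c(`0-17` = 0L, `18-34` = 18L, `35-44` = 35L, `45-64` = 45L, `65+` = 65L)
    hi <- c(`0-17` = 17L, `18-34` = 34L, `35-44` = 44L, `45-64` = 64L, `65+` = 90L)
    age <- ifelse(is.na(val), NA_integer_,
                  lo[val] + floor(stats::runif(n_users) * (hi[val] - lo[val] + 1L)))
    users$age_years <- as.integer(age)
  } else if (config$attribute == "region") {
    st <- rep(NA_character_, n_users)
    for (r in names(.region_states)) {
      i <- which(!is.na(val) & val == r)
      if (length(i) > 0L)
        st[i] <- sample(.region_states[[r]], length(i), replace = TRUE)
    }
    users$location_state <- st
  }

  posts <- posts_tibble(
    post_id = sprintf("p%07d", seq_len(n_posts)),
    user_id = user_ids[user_of_post],
    text = texts,
    source = config$source
  )

  planted_truth <- NULL
  if (nrow(pt) > 0L) {
    planted_truth <- do.call(rbind, lapply(seq_len(nrow(pt)), function(i) {
      rates <- ifelse(groups == pt$target_group[i],
                      pt$rate_in_target[i], pt$rate_elsewhere[i])
      tibble::tibble(term = pt$term[i], group = groups,
                     target_group = pt$target_group[i], rate = rates,
                     expected_rel_dif = .expected_reldif(rates))
    }))
  }
  emotion_truth <- do.call(rbind, lapply(groups, function(g) {
    ei <- config$emotion_injection[[g]]
    tibble::tibble(group = g, emotion = names(ei),
                   expected_pct = 100 * unname(ei))
  }))

  list(posts = posts, users = users,
       manifest = list(planted = planted_truth, emotions = emotion_truth,
                       attribute = config$attribute, groups = groups,
                       posts_per_group = npg, seed = config$seed))
}

#' Write fixture lexicons and dictionaries
#'
#' Emits, in the exact dialects the loaders consume: a sentiment lexicon
#' whose rows satisfy pos+neg+obj = 1 and cover the generator's injected
#' sentiment words, an emotion lexicon covering the generator's emotion
#' pools, a ~50-concept medical dictionary including multiword synonyms
#' ("heart attack") and a blacklisted surface form ("i" as an
#' immunologic-factor concept), a health-keyword list, the blacklist, a
#' stop-word list and first/last name tables. All content is deterministic;
#' `seed` only shuffles row order of the name tables.
#'
#' @param dir output directory (created if needed).
#' @param seed integer.
#' @return invisibly, named vector of the file paths.
#' @export
generate_fixture_lexicons <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- c(
    sentiment = file.path(dir, "sentiment.tsv"),
    emotion = file.path(dir, "emotions.tsv"),
    concepts = file.path(dir, "concepts.tsv"),
    blacklist = file.path(dir, "blacklist.tsv"),
    keywords = file.path(dir, "keywords.tsv"),
    stopwords = file.path(dir, "stopwords.txt"),
    names_first = file.path(dir, "names_first.tsv"),
    names_last = file.path(dir, "names_last.tsv")
  )

  sent <- c(
    "# POS\tterm(s)\tPosScore\tNegScore",
    "a\twonderful\t0.75\t0",
    "a\texcellent\t0.875\t0",
    "a\tamazing\t0.75\t0.125",
    "n\trelief\t0.625\t0",
    "a\thelpful\t0.625\t0",
    "a\tterrible\t0\t0.75",
    "a\tawful\t0\t0.875",
    "a\tpainful\t0\t0.75",
    "a\thorrible\t0.125\t0.75",
    "a\tunbearable\t0\t0.625",
    "a\tgood\t0.625\t0",
    "a\tbad\t0\t0.625",
    "n\theadache\t0\t0.375",
    "v\thurt\t0\t0.5",
    "n\theart_attack\t0\t0.25",
    "r\tquickly\t0.125\t0",
    "n\tmedicine\t0.125\t0"
  )
  writeLines(sent, paths["sentiment"])

  emo <- unlist(lapply(names(.gen_emotion_pools), function(e) {
    sprintf("%s\t%s\t1", .gen_emotion_pools[[e]], e)
  }))
  # a couple of words carrying two emotions, as in the real lexicon
  emo <- c(emo, "terrified\tsadness\t1", "awaiting\ttrust\t1",
           "furious\tdisgust\t1", "wonderful\tjoy\t0")
  writeLines(emo, paths["emotion"])

  concepts <- c(
    "C0027051\tMyocardial infarction\tMI|myocardial infarction|heart attack\tDisorders",
    "C0018681\tHeadache\theadache|headaches|cephalalgia\tDisorders",
    "C0011849\tDiabetes mellitus\tdiabetes|diabetes mellitus\tDisorders",
    "C0004096\tAsthma\tasthma\tDisorders",
    "C0011570\tDepression\tdepression|depressed mood\tDisorders",
    "C0003123\tAnorexia\tanorexia\tDisorders",
    "C0020538\tHypertension\thypertension|high blood pressure\tDisorders",
    "C0002395\tAlzheimer disease\talzheimer|alzheimers disease\tDisorders",
    "C0006826\tCancer\tcancer|malignant tumor\tDisorders",
    "C0011847\tDiabetic\tdiabetic\tDisorders",
    "C0015967\tFever\tfever|pyrexia\tDisorders",
    "C0026769\tMultiple sclerosis\tmultiple sclerosis|ms disorder\tDisorders",
    "C0004352\tAutism\tautism\tDisorders",
    "C1263846\tADHD\tadhd|attention deficit hyperactivity disorder\tDisorders",
    "C0011991\tDiarrhea\tdiarrhea\tDisorders",
    "C0021400\tInfluenza\tinfluenza|flu\tDisorders",
    "C0023890\tCirrhosis\tcirrhosis\tDisorders",
    "C0038436\tStroke\tstroke|cerebrovascular accident\tDisorders",
    "C0003864\tArthritis\tarthritis\tDisorders",
    "C0010054\tCoronary arteriosclerosis\tcoronary arteriosclerosis\tDisorders",
    "C0019158\tHepatitis\thepatitis\tDisorders",
    "C0033975\tPsychosis\tpsychosis\tDisorders",
    "C0036341\tSchizophrenia\tschizophrenia\tDisorders",
    "C0011253\tDementia\tdementia\tDisorders",
    "C0027497\tNausea\tnausea\tDisorders",
    "C0004238\tAtrial fibrillation\tatrial fibrillation\tDisorders",
    "C0002871\tAnemia\tanemia\tDisorders",
    "C0149931\tMigraine\tmigraine|migraines\tDisorders",
    "C0030193\tPain\tpain|ache\tDisorders",
    "C0022104\tIrritable bowel syndrome\tirritable bowel syndrome|ibs\tDisorders",
    "C0699142\tTylenol\ttylenol\tChemicals & Drugs",
    "C0593507\tAdvil\tadvil\tChemicals & Drugs",
    "C0699203\tMotrin\tmotrin\tChemicals & Drugs",
    "C0065374\tLisinopril\tlisinopril\tChemicals & Drugs",
    "C0728762\tXanax\txanax\tChemicals & Drugs",
    "C0724441\tProzac\tprozac\tChemicals & Drugs",
    "C0678180\tZoloft\tzoloft\tChemicals & Drugs",
    "C0025598\tMetformin\tmetformin\tChemicals & Drugs",
    "C0593906\tLipitor\tlipitor\tChemicals & Drugs",
    "C0021641\tInsulin\tinsulin\tChemicals & Drugs",
    "C0004057\tAspirin\taspirin\tChemicals & Drugs",
    "C0700899\tConcerta\tconcerta\tChemicals & Drugs",
    "C1170050\tVyvanse\tvyvanse\tChemicals & Drugs",
    "C0721754\tStrattera\tstrattera\tChemicals & Drugs",
    "C0699129\tPlavix\tplavix\tChemicals & Drugs",
    "C0875968\tDiovan\tdiovan\tChemicals & Drugs",
    "C0723277\tValium\tvalium\tChemicals & Drugs",
    "C0002800\tImmunologic factor\ti|immunologic factor\tChemicals & Drugs",
    "C0018787\tHeart\theart\tAnatomy",
    "C0023216\tLeg\tleg\tAnatomy",
    "C0455873\tBad\tbad\tChemicals & Drugs"
  )
  writeLines(concepts, paths["concepts"])

  writeLines(c("i\tC0002800", "bad\tC0455873"), paths["blacklist"])

  kw <- c(
    "lisinopril\tdrug", "metformin\tdrug", "xanax\tdrug", "prozac\tdrug",
    "zoloft\tdrug", "lipitor\tdrug", "insulin\tdrug", "aspirin\tdrug",
    "tylenol\tdrug", "advil\tdrug", "concerta\tdrug", "vyvanse\tdrug",
    "plavix\tdrug", "diovan\tdrug", "valium\tdrug", "adderall\tdrug",
    "#bcsm\thashtag", "#hcsm\thashtag", "#meded\thashtag", "#mhsm\thashtag",
    "aids\tdisorder", "asthma\tdisorder", "diabetes\tdisorder",
    "cancer\tdisorder", "depression\tdisorder", "migraine\tdisorder",
    "headache\tdisorder", "stroke\tdisorder", "arthritis\tdisorder",
    "adhd\tdisorder", "flu\tdisorder", "anemia\tdisorder",
    "heart attack\tdisorder", "high blood pressure\tdisorder",
    "novartis\tpharma", "pfizer\tpharma", "merck\tpharma",
    "aetna\tinsurance", "cigna\tinsurance", "humana\tinsurance"
  )
  writeLines(kw, paths["keywords"])

  writeLines(.default_stopwords, paths["stopwords"])

  nf <- c(
    "mary\tfemale\t0.996", "mary\tmale\t0.004",
    "james\tmale\t0.995", "james\tfemale\t0.005",
    "linda\tfemale\t0.997", "linda\tmale\t0.003",
    "robert\tmale\t0.996", "robert\tfemale\t0.004",
    "patricia\tfemale\t0.995", "patricia\tmale\t0.005",
    "john\tmale\t0.994", "john\tfemale\t0.006",
    "jordan\tmale\t0.55", "jordan\tfemale\t0.45",
    "taylor\tfemale\t0.62", "taylor\tmale\t0.38"
  )
  writeLines(nf[sample(seq_along(nf))], paths["names_first"])

  nl <- c(
    "smith\twhite\t0.73", "smith\tblack\t0.22", "smith\tasian\t0.01",
    "smith\thispanic\t0.04",
    "garcia\thispanic\t0.93", "garcia\twhite\t0.05", "garcia\tblack\t0.01",
    "garcia\tasian\t0.01",
    "nguyen\tasian\t0.96", "nguyen\twhite\t0.02", "nguyen\tblack\t0.01",
    "nguyen\thispanic\t0.01",
    "washington\tblack\t0.87", "washington\twhite\t0.1", "washington\tasian\t0.01",
    "washington\thispanic\t0.02",
    "yoder\twhite\t0.985", "yoder\tblack\t0.005", "yoder\tasian\t0.005",
    "yoder\thispanic\t0.005",
    "martinez\thispanic\t0.92", "martinez\twhite\t0.06", "martinez\tblack\t0.01",
    "martinez\tasian\t0.01",
    "lee\tasian\t0.45", "lee\twhite\t0.38", "lee\tblack\t0.15",
    "lee\thispanic\t0.02"
  )
  writeLines(nl[sample(seq_along(nl))], paths["names_last"])

  invisible(paths)
}

.default_stopwords <- c(
  "a", "about", "above", "after", "again", "against", "all", "am", "an",
  "and", "any", "are", "as", "at", "be", "because", "been", "before",
  "being", "below", "between", "both", "but", "by", "can", "could", "did",
  "do", "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "him", "his", "how", "i", "if", "in", "into", "is", "it", "its", "itself",
  "just", "me", "more", "most", "my", "myself", "no", "nor", "not", "now",
  "of", "off", "on", "once", "only", "or", "other", "our", "ours", "out",
  "over", "own", "same", "she", "should", "so", "some", "such", "than",
  "that", "the", "their", "theirs", "them", "then", "there", "these",
  "they", "this", "those", "through", "to", "too", "under", "until", "up",
  "very", "was", "we", "were", "what", "when", "where", "which", "while",
  "who", "whom", "why", "will", "with", "would", "you", "your", "yours",
  "yourself"
)
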
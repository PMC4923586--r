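# Distinctive-item analysis: per-group frequencies, relative differences,
# occurrence thresholding, top-k reporting. Works identically on term stems
# and on concept ids.

#' Minimum occurrence threshold
#'
#' An item must occur in at least 0.01% of the posts annotated for the
#' attribute, with a floor of 30 occurrences when 0.01% falls below 30:
#' `max(0.0001 * n, 30)`.
#'
#' @param n_annotated_posts total posts annotated for the attribute.
#' @return numeric threshold.
#' @examples
#' min_occurrence_threshold(c(50000, 300000, 1e6))  # 30, 30, 100
#' @export
min_occurrence_threshold <- function(n_annotated_posts) {
  stopifnot(all(n_annotated_posts >= 0))
  pmax(1e-4 * n_annotated_posts, 30)
}

#' Per-group item frequency table
#'
#' Implements the frequency normalization: occurrences of an item in a
#' group's posts divided by the number of posts in that group. Items whose
#' total occurrences across all annotated posts fall below
#' [min_occurrence_threshold()] are removed; for term streams, stop-word
#' stems are removed first.
#'
#' @param partition named list group -> post tibble, from [partition_posts()].
#' @param items_by_post tibble/data.table with columns `post_id` and `item`
#'   (one row per occurrence) — term stems or concept ids.
#' @param drop_stopwords remove items that are stop-word stems.
#' @param count a switch between counting every occurrence (`"occurrences"`,
#'   the default) and counting distinct posts containing the item (`"posts"`).
#' @return list: `freq` tibble (`item`, `group`, `n_occurrences`, `freq`),
#'   `n_posts` named vector, `threshold` used, `n_annotated` total.
#' @export
build_freq_table <- function(partition, items_by_post, drop_stopwords = TRUE,
                             count = c("occurrences", "posts")) {
  count <- match.arg(count)
  if (length(partition) < 2L)
    stop("need at least 2 groups to compute relative differences")
  stopifnot(all(vapply(partition, nrow, integer(1)) >= 1L))
  items <- data.table::as.data.table(items_by_post)
  stopifnot(all(c("post_id", "item") %in% names(items)))
  if (drop_stopwords) {
    sw_stems <- unique(porter_stem(stopword_list()))
    items <- items[!item %chin% c(stopword_list(), sw_stems)]
  }
  n_posts <- vapply(partition, nrow, integer(1))
  n_annotated <- sum(n_posts)
  thr <- min_occurrence_threshold(n_annotated)

  grp_of <- rep(names(partition), n_posts)
  names(grp_of) <- unlist(lapply(partition, function(p) p$post_id), use.names = FALSE)
  items[, group := grp_of[post_id]]
  items <- items[!is.na(group)]
  if (count == "posts") items <- unique(items, by = c("post_id", "item"))

  tot <- items[, .(total = .N), by = item]
  keep <- tot[total >= thr, item]
  items <- items[item %chin% keep]
  freq <- items[, .(n_occurrences = .N), by = .(item, group)]
  freq[, freq := n_occurrences / n_posts[group]]
  list(freq = tibble::as_tibble(freq), n_posts = n_posts, threshold = thr,
       n_annotated = n_annotated)
}

#' Relative differences across groups
#'
#' For each surviving item, the average frequency is the unweighted mean of
#' its per-group frequencies (groups where it never occurs contribute 0), and
#' each group's relative difference is
#' `(freq_g - avg_freq) / avg_freq`. By construction the relative
#' differences of an item sum to zero across groups.
#'
#' @param table result of [build_freq_table()].
#' @return tibble with `item`, `group`, `freq`, `avg_freq`, `rel_dif`.
#' @export
relative_differences <- function(table) {
  freq <- data.table::as.data.table(table$freq)
  groups <- names(table$n_posts)
  if (nrow(freq) == 0L)
    return(tibble::tibble(item = character(0), group = character(0),
                          freq = numeric(0), avg_freq = numeric(0),
                          rel_dif = numeric(0)))
  full <- data.table::CJ(item = unique(freq$item), group = groups)
  full <- merge(full, freq[, .(item, group, freq)], by = c("item", "group"),
                all.x = TRUE)
  full[is.na(freq), freq := 0]
  full[, avg_freq := mean(freq), by = item]
  full[, rel_dif := (freq - avg_freq) / avg_freq]
  tibble::as_tibble(full[, .(item, group, freq, avg_freq, rel_dif)])
}

#' Top distinctive items per group
#'
#' Keeps items whose relative difference exceeds `min_reldif` (the display
#' rule hiding items within 10% of the cross-group average), sorts each
#' group descending by relative difference — ties broken by higher average
#' frequency, then lexicographically — and truncates to `k`. An optional
#' allow/block display filter (the reproducible analogue of a manual
#' health-relatedness screen) is applied before truncation.
#'
#' @param results tibble from [relative_differences()].
#' @param k list length per group.
#' @param min_reldif display threshold on the relative difference.
#' @param allow,block optional character vectors of items to keep / remove
#'   before ranking.
#' @return tibble with `group`, `rank`, `item`, `freq`, `avg_freq`,
#'   `rel_dif`; groups where nothing exceeds the threshold are absent.
#' @export
top_distinctive <- function(results, k = 10L, min_reldif = 0.1,
                            allow = NULL, block = NULL) {
  dt <- data.table::as.data.table(results)
  if (!is.null(allow)) dt <- dt[item %chin% allow]
  if (!is.null(block)) dt <- dt[!item %chin% block]
  dt <- dt[rel_dif > min_reldif]
  if (nrow(dt) == 0L)
    return(tibble::tibble(group = character(0), rank = integer(0),
                          item = character(0), freq = numeric(0),
                          avg_freq = numeric(0), rel_dif = numeric(0)))
  data.table::setorder(dt, group, -rel_dif, -avg_freq, item)
  dt[, rank := seq_len(.N), by = group]
  dt <- dt[rank <= k]
  tibble::as_tibble(dt[, .(group, rank, item, freq, avg_freq, rel_dif)])
}

#' Term stream for distinctive-term analysis
#'
#' Tokenizes posts and emits one row per non-stop-word token occurrence,
#' keyed by stem — the input stream for [build_freq_table()].
#'
#' @param posts post tibble.
#' @return tibble with `post_id`, `item`.
#' @export
term_stream <- function(posts) {
  dt <- .tokenize_corpus(posts$text, posts$post_id)
  tibble::as_tibble(dt[is_stopword == FALSE, .(post_id, item = stem)])
}

#' Concept stream for distinctive-concept analysis
#'
#' @param annotations tibble from [annotate_posts()].
#' @param group optional semantic group to restrict to (e.g. `"Disorders"`).
#' @return tibble with `post_id`, `item` (concept ids).
#' @export
concept_stream <- function(annotations, group = NULL) {
  a <- annotations
  if (!is.null(group)) a <- a[a$semantic_group == group, , drop = FALSE]
  tibble::tibble(post_id = a$post_id, item = a$concept_id)
}
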
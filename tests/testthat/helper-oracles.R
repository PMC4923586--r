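# Independent oracle implementations and tiny fixture builders shared by the
# tests. The oracles deliberately avoid the package's indexing/aggregation
# code paths: plain loops, table() counts, whole-table scans.

extdata <- function(f) system.file("extdata", f, package = "demotext")

# Brute-force recount of the distinctive-term chain: tokenization by simple
# regex split, occurrence counts via table(), threshold / Eq 1 / Eq 2 inline.
oracle_distinctive <- function(partition) {
  sw <- stopword_list()
  sw_all <- union(sw, porter_stem(sw))
  counts <- list()
  n_posts <- integer(0)
  for (g in names(partition)) {
    stems_all <- character(0)
    for (tx in partition[[g]]$text) {
      toks <- unlist(strsplit(tolower(tx), "[^a-z0-9#_']+"))
      toks <- toks[nzchar(toks)]
      stems <- porter_stem(toks)
      stems_all <- c(stems_all, stems[!stems %in% sw_all])
    }
    counts[[g]] <- table(stems_all)
    n_posts[g] <- nrow(partition[[g]])
  }
  all_items <- sort(unique(unlist(lapply(counts, names))))
  totals <- sapply(all_items, function(it)
    sum(sapply(counts, function(ct) if (it %in% names(ct)) ct[[it]] else 0)))
  thr <- max(1e-4 * sum(n_posts), 30)
  keep <- all_items[totals >= thr]
  out <- NULL
  for (it in keep) {
    freqs <- sapply(names(partition), function(g)
      (if (it %in% names(counts[[g]])) counts[[g]][[it]] else 0) / n_posts[[g]])
    avg <- mean(freqs)
    out <- rbind(out, data.frame(item = it, group = names(partition),
                                 freq = unname(freqs), avg_freq = avg,
                                 rel_dif = unname((freqs - avg) / avg)))
  }
  out
}

# Exhaustive maximal left-to-right matcher: scans every entry at every
# position, no first-stem index, no early exit.
oracle_match <- function(stems, lexicon_entries) {
  n <- length(stems)
  res <- NULL
  i <- 1
  while (i <= n) {
    best_len <- 0; best_key <- NA_character_
    for (j in seq_len(nrow(lexicon_entries))) {
      key <- lexicon_entries$stems[j]
      kt <- strsplit(key, " ", fixed = TRUE)[[1]]
      L <- length(kt)
      if (L > n - i + 1) next
      if (all(stems[i:(i + L - 1)] == kt) && L > best_len) {
        best_len <- L; best_key <- key
      }
    }
    if (best_len > 0) {
      res <- rbind(res, data.frame(start = i, length = best_len,
                                   stems = best_key))
      i <- i + best_len
    } else i <- i + 1
  }
  res
}

# small deterministic corpus: two genders, hand-countable texts
tiny_corpus <- function() {
  posts <- posts_tibble(
    post_id = sprintf("p%02d", 1:10),
    user_id = c("u1", "u1", "u2", "u3", "u4", "u5", "u5", "u6", "u7", "u8"),
    text = c("headache again", "bad headache today", "feeling wonderful",
             "my asthma acts up", "heart attack scare", "just music",
             "more music", "took lisinopril", "awful migraine",
             "flu season again"),
    source = "forum"
  )
  users <- users_tibble(
    user_id = sprintf("u%d", 1:8),
    first_name = c("Mary", "James", "Linda", "Robert", NA, "Patricia", "John", "Jordan"),
    gender = c("female", "male", "female", "male", NA, "female", NA, NA),
    age_years = c(17L, 30L, 40L, 50L, 70L, NA, 25L, 35L),
    location_state = c("NY", "CA", "TX", "IL", "MA", "WA", NA, "GA")
  )
  list(posts = posts, users = users)
}

write_temp_lexicon <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
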
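# Demographic inference: first-name gender, surname ethnicity, and
# Flesch-Kincaid writing level with binning.

#' Load a name-frequency table
#'
#' TSV dialect `name<TAB>label<TAB>share` where the shares of one name sum
#' to 1 across labels — the layout SSA baby-name counts and Census surname
#' percentages reduce to after normalization.
#'
#' @param path table file.
#' @return tibble with lowercase `name`, `label`, `share`.
#' @export
load_name_table <- function(path) {
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("name", "label", "share"))
  dt[, name := stringi::stri_trans_tolower(name)]
  tot <- dt[, .(s = sum(share)), by = name]
  bad <- abs(tot$s - 1) > 1e-6
  if (any(bad))
    stop("name shares do not sum to 1: ",
         paste(utils::head(tot$name[bad], 3), collapse = ", "))
  tibble::as_tibble(dt)
}

.classify_name <- function(names, table, dominance, labels) {
  dt <- data.table::as.data.table(table)
  key <- stringi::stri_trans_tolower(trimws(names))
  out <- rep("unknown", length(names))
  for (i in seq_along(key)) {
    if (is.na(key[i]) || !nzchar(key[i])) next
    rows <- dt[name == key[i]]
    if (nrow(rows) == 0L) next
    j <- which.max(rows$share)
    if (rows$share[j] >= dominance && rows$label[j] %in% labels)
      out[i] <- rows$label[j]
  }
  out
}

#' Classify gender from a first name
#'
#' Returns the label whose share of the name reaches the dominance
#' threshold; ambiguous or unseen names stay `unknown`. Case-insensitive.
#'
#' @param first_name character vector.
#' @param table tibble from [load_name_table()] with labels male/female.
#' @param dominance minimum share required to assign a label; the default
#'   0.95 favours precision over coverage.
#' @return character vector in `{male, female, unknown}`.
#' @export
classify_gender <- function(first_name, table, dominance = 0.95) {
  .classify_name(first_name, table, dominance, .genders)
}

#' Classify ethnicity from a surname
#'
#' @param last_name character vector.
#' @param table tibble from [load_name_table()] with labels
#'   white/black/asian/hispanic.
#' @param dominance minimum share, default 0.80.
#' @return character vector in `{white, black, asian, hispanic, unknown}`.
#' @export
classify_ethnicity <- function(last_name, table, dominance = 0.80) {
  .classify_name(last_name, table, dominance, .ethnicities)
}

# Syllable heuristic: count maximal vowel groups (a,e,i,o,u,y), subtract a
# trailing silent 'e' (but not '-le' after a consonant), floor at 1.
.count_syllables <- function(words) {
  w <- stringi::stri_trans_tolower(words)
  groups <- stringi::stri_count_regex(w, "[aeiouy]+")
  silent_e <- grepl("[^aeiouy]e$", w) & !grepl("[^aeiouy]le$", w) & groups > 1L
  pmax(groups - as.integer(silent_e), 1L)
}

#' Flesch-Kincaid grade of a text
#'
#' `0.39 * words/sentences + 11.8 * syllables/words - 15.59`, with the
#' modifications documented for this pipeline: sentences counted from
#' terminal punctuation (`.?!`, minimum 1), syllables from a vowel-group
#' heuristic with a silent-e rule (minimum 1 per word), and the result
#' clamped to \[0, 16\] so that the writing-level bins cover the range.
#'
#' @param text character vector of texts.
#' @return numeric vector of clamped grades; `NA` for texts with no words.
#' @examples
#' grade_text("The cat sat on the mat.")  # 6 monosyllables -> clamps to 0
#' @export
grade_text <- function(text) {
  vapply(text, function(tx) {
    if (is.na(tx)) return(NA_real_)
    words <- stringi::stri_extract_all_regex(
      stringi::stri_trans_tolower(tx), "[\\p{L}\\p{N}']+")[[1]]
    words <- words[!is.na(words)]
    if (length(words) == 0L) return(NA_real_)
    sentences <- max(1L, stringi::stri_count_regex(tx, "[.?!]+"))
    syl <- sum(.count_syllables(words))
    g <- 0.39 * length(words) / sentences + 11.8 * syl / length(words) - 15.59
    min(max(g, 0), 16)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Writing level of a user
#'
#' The user's grade is the mean of their per-post grades (each post weighted
#' equally, so prolific users do not change the formula's inputs), binned
#' per [bin_writing_level()].
#'
#' @param texts the user's post texts.
#' @return list `grade`, `n_posts_used`, `bin`; all `NA` when no post is
#'   gradeable.
#' @export
user_writing_level <- function(texts) {
  g <- grade_text(texts)
  g <- g[!is.na(g)]
  if (length(g) == 0L)
    return(list(grade = NA_real_, n_posts_used = 0L, bin = NA_character_))
  m <- mean(g)
  list(grade = m, n_posts_used = length(g), bin = bin_writing_level(m))
}

#' Fill missing demographics across a corpus
#'
#' Applies the name classifiers to users with missing gender/ethnicity and
#' computes each user's writing level from their posts; inferred values are
#' marked `classified` in the provenance columns, reported values are left
#' untouched.
#'
#' @param posts,users corpus tibbles.
#' @param first_table,last_table name tables ([load_name_table()]), or `NULL`
#'   to skip that classifier.
#' @param gender_dominance,ethnicity_dominance classifier thresholds.
#' @return `users` with gaps filled and provenance updated.
#' @export
infer_demographics <- function(posts, users, first_table = NULL,
                               last_table = NULL, gender_dominance = 0.95,
                               ethnicity_dominance = 0.80) {
  u <- users
  if (!is.null(first_table)) {
    todo <- is.na(u$gender) & !is.na(u$first_name)
    if (any(todo)) {
      lab <- classify_gender(u$first_name[todo], first_table, gender_dominance)
      hit <- lab != "unknown"
      u$gender[todo][hit] <- lab[hit]
      u$gender_provenance[todo][hit] <- "classified"
    }
  }
  if (!is.null(last_table)) {
    todo <- is.na(u$ethnicity) & !is.na(u$last_name)
    if (any(todo)) {
      lab <- classify_ethnicity(u$last_name[todo], last_table, ethnicity_dominance)
      hit <- lab != "unknown"
      u$ethnicity[todo][hit] <- lab[hit]
      u$ethnicity_provenance[todo][hit] <- "classified"
    }
  }
  todo <- is.na(u$writing_level_grade)
  if (any(todo)) {
    by_user <- split(posts$text, posts$user_id)
    for (i in which(todo)) {
      texts <- by_user[[u$user_id[i]]]
      if (is.null(texts)) next
      wl <- user_writing_level(texts)
      if (!is.na(wl$grade)) {
        u$writing_level_grade[i] <- wl$grade
        u$writing_level_provenance[i] <- "classified"
      }
    }
  }
  u
}
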
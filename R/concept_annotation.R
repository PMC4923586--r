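# Dictionary-based medical concept annotation: a longest-match stand-in for
# MetaMap, with a misclassification blacklist and semantic-group restriction.

.semantic_groups <- c(
  "Activities & Behaviors", "Anatomy", "Chemicals & Drugs", "Concepts & Ideas",
  "Devices", "Disorders", "Genes & Molecular Sequences", "Geographic Areas",
  "Living Beings", "Objects", "Occupations", "Organizations", "Phenomena",
  "Physiology", "Procedures")

#' The 15 UMLS semantic groups
#'
#' @return character vector of the coarse semantic-group labels concepts may
#'   carry; only `Disorders` and `Chemicals & Drugs` are analyzed by default.
#' @export
semantic_groups <- function() .semantic_groups

#' Load a medical-concept dictionary
#'
#' TSV dialect: `concept_id<TAB>preferred_name<TAB>synonyms<TAB>semantic_group`
#' with `|`-separated synonyms (multiword synonyms space-separated inside).
#' Synonyms are normalized with the same pipeline as posts (lowercased,
#' Porter-stemmed), rows with an unknown semantic group are rejected, and
#' rows sharing a `concept_id` are merged (synonym union).
#'
#' @param path dictionary file.
#' @return a lexicon index (see [match_phrases()]) whose `$entries` carry
#'   `concept_id`, `preferred_name`, `semantic_group`.
#' @export
load_concept_dictionary <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0L) stop("empty concept dictionary: ", path)
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("concept_id", "preferred_name",
                                        "synonyms", "semantic_group"))
  if (nrow(dt) == 0L) stop("empty concept dictionary: ", path)
  bad <- !dt$semantic_group %in% .semantic_groups
  if (any(bad))
    stop("unknown semantic group(s): ",
         paste(unique(dt$semantic_group[bad]), collapse = ", "))
  dt <- dt[, .(preferred_name = preferred_name[1L],
               semantic_group = semantic_group[1L],
               synonyms = paste(synonyms, collapse = "|")),
           by = concept_id]
  rows <- dt[, .(synonym = strsplit(synonyms, "|", fixed = TRUE)[[1L]]),
             by = .(concept_id, preferred_name, semantic_group)]
  rows[, stems := .phrase_key(synonym)]
  rows <- rows[nzchar(stems)]
  rows <- unique(rows, by = c("concept_id", "stems"))
  ent <- rows[, .(stems, pos = "any", concept_id, preferred_name,
                  semantic_group, surface = synonym)]
  .build_lexicon_index(ent)
}

#' Load a concept blacklist
#'
#' TSV of `(surface form, concept_id)` pairs to suppress — the reproducible
#' replacement for manually deleting misclassified annotations (e.g. the
#' bare letter "i" tagged as an immunologic factor).
#'
#' @param path blacklist file, or `NULL` for an empty blacklist.
#' @return tibble with `surface` (lowercase) and `concept_id`.
#' @export
load_blacklist <- function(path = NULL) {
  if (is.null(path)) return(tibble::tibble(surface = character(0),
                                           concept_id = character(0)))
  stopifnot(file.exists(path))
  dt <- data.table::fread(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("surface", "concept_id"))
  tibble::tibble(surface = stringi::stri_trans_tolower(dt$surface),
                 concept_id = as.character(dt$concept_id))
}

#' Annotate a post with medical concepts
#'
#' Greedy longest-match of the post's normalized tokens against the concept
#' dictionary (same matcher contract as sentiment scoring, so "heart attack"
#' is annotated once as a two-token Disorders concept and the lone token
#' "heart" is not separately matched). Blacklisted (surface, concept) pairs
#' are dropped, then concepts outside `groups_kept` are dropped.
#'
#' @param text post text.
#' @param dictionary index from [load_concept_dictionary()].
#' @param blacklist tibble from [load_blacklist()].
#' @param groups_kept semantic groups retained in the output.
#' @return tibble with `concept_id`, `matched_surface`, `semantic_group`,
#'   `preferred_name`, one row per occurrence.
#' @export
annotate_post <- function(text, dictionary, blacklist = load_blacklist(),
                          groups_kept = c("Disorders", "Chemicals & Drugs")) {
  toks <- normalize_text(text)
  .annotate_tokens(toks$surface, toks$stem, dictionary, blacklist, groups_kept)
}

.annotate_tokens <- function(surfaces, stems, dictionary, blacklist, groups_kept) {
  td <- tibble::tibble(surface = surfaces, stem = stems,
                       is_stopword = rep(FALSE, length(stems)))
  m <- match_phrases(td, dictionary)
  ent <- dictionary$entries
  if (nrow(m) == 0L)
    return(tibble::tibble(concept_id = character(0),
                          matched_surface = character(0),
                          semantic_group = character(0),
                          preferred_name = character(0)))
  matched_surface <- vapply(seq_len(nrow(m)), function(i) {
    paste(surfaces[m$start[i]:(m$start[i] + m$length[i] - 1L)], collapse = " ")
  }, character(1))
  out <- tibble::tibble(concept_id = ent$concept_id[m$entry_id],
                        matched_surface = matched_surface,
                        semantic_group = ent$semantic_group[m$entry_id],
                        preferred_name = ent$preferred_name[m$entry_id])
  if (nrow(blacklist) > 0L) {
    key <- paste(stringi::stri_trans_tolower(out$matched_surface), out$concept_id)
    drop <- key %in% paste(blacklist$surface, blacklist$concept_id)
    out <- out[!drop, , drop = FALSE]
  }
  out[out$semantic_group %in% groups_kept, , drop = FALSE]
}

#' Annotate every post in a corpus
#'
#' @param posts post tibble.
#' @inheritParams annotate_post
#' @return tibble keyed by `post_id` with one row per concept occurrence.
#' @export
annotate_posts <- function(posts, dictionary, blacklist = load_blacklist(),
                           groups_kept = c("Disorders", "Chemicals & Drugs")) {
  dt <- .tokenize_corpus(posts$text, posts$post_id)
  by_post <- split(dt, by = "post_id", sorted = FALSE)
  res <- lapply(names(by_post), function(pid) {
    td <- by_post[[pid]]
    a <- .annotate_tokens(td$surface, td$stem, dictionary, blacklist, groups_kept)
    if (nrow(a) == 0L) return(NULL)
    cbind(tibble::tibble(post_id = rep(pid, nrow(a))), a)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L)
    return(tibble::tibble(post_id = character(0), concept_id = character(0),
                          matched_surface = character(0),
                          semantic_group = character(0),
                          preferred_name = character(0)))
  tibble::as_tibble(do.call(rbind, res))
}

#' Concept frequency report
#'
#' Orders annotations by frequency for manual review — the reproducible
#' analogue of inspecting the most frequent mappings and growing the
#' blacklist from what turns out to be misclassified.
#'
#' @param annotations tibble from [annotate_posts()].
#' @return tibble of `concept_id`, `preferred_name`, `semantic_group`,
#'   `n_occurrences`, `example_surfaces`, sorted by descending frequency.
#' @export
concept_frequency_report <- function(annotations) {
  dt <- data.table::as.data.table(annotations)
  rep <- dt[, .(n_occurrences = .N,
                example_surfaces = paste(utils::head(unique(matched_surface), 3),
                                         collapse = "; ")),
            by = .(concept_id, preferred_name, semantic_group)]
  data.table::setorder(rep, -n_occurrences, concept_id)
  tibble::as_tibble(rep)
}
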
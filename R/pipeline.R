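# End-to-end orchestration: read -> relevance filter -> demographic
# inference -> sentiment/emotion scoring -> concept annotation ->
# distinctive analysis, with per-stage counts and reproducible outputs.

#' Read a run configuration
#'
#' YAML (or JSON) file with the fields of the list accepted by
#' [run_pipeline()]: input paths (`corpus`, `sentiment_lexicon`,
#' `emotion_lexicon`, `concepts`, `blacklist`, `keywords`, `names_first`,
#' `names_last`), `attributes`, `out_dir`, and thresholds (`k`,
#' `min_reldif`, `alpha`, `gender_dominance`, `ethnicity_dominance`,
#' `seed`). Referenced input files must exist.
#'
#' @param path config file.
#' @return the validated config list.
#' @export
read_run_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  .validate_config(cfg)
}

.validate_config <- function(cfg) {
  defaults <- list(attributes = "gender", k = 10L, min_reldif = 0.1,
                   alpha = 0.05, gender_dominance = 0.95,
                   ethnicity_dominance = 0.80, seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  req <- c("corpus", "sentiment_lexicon", "emotion_lexicon", "concepts",
           "keywords", "out_dir")
  miss <- setdiff(req, names(cfg))
  if (length(miss) > 0L) stop("config missing fields: ", paste(miss, collapse = ", "))
  files <- c(paste0(cfg$corpus, ".posts.jsonl"), paste0(cfg$corpus, ".users.jsonl"),
             cfg$sentiment_lexicon, cfg$emotion_lexicon, cfg$concepts,
             cfg$keywords, cfg$blacklist, cfg$names_first, cfg$names_last)
  for (f in files) if (!is.null(f) && !file.exists(f))
    stop("config references missing file: ", f)
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Render a per-group emotion table
#'
#' One row per group, one column per reported emotion holding the percentage
#' rounded to one decimal with a `*` marker on cells whose group-vs-rest
#' comparison is significant — the machine twin of a published
#' emotion-by-demographic table.
#'
#' @param emotions long tibble from [aggregate_groups()].
#' @param report which emotions become columns (default the six paired ones).
#' @return wide tibble of formatted cells.
#' @export
report_emotion_table <- function(emotions,
                                 report = c("anger", "fear", "trust",
                                            "disgust", "anticipation",
                                            "surprise")) {
  stopifnot(nrow(emotions) > 0L)
  groups <- unique(emotions$group)
  rows <- lapply(groups, function(g) {
    row <- list(group = g)
    for (e in report) {
      cell <- emotions[emotions$group == g & emotions$emotion == e, ]
      row[[e]] <- if (nrow(cell) == 0L) "" else
        paste0(formatC(cell$percentage, format = "f", digits = 1),
               if (isTRUE(cell$significant)) "*" else "")
    }
    tibble::as_tibble(row)
  })
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Executes every stage over the configured corpus and writes, per
#' demographic attribute: distinctive terms, distinctive disorders,
#' distinctive drugs, a sentiment table and an emotion table with
#' significance markers, plus a run manifest (config hash, seed, per-stage
#' counts) that makes the run reproducible. Stage failures abort with the
#' stage name. Outputs are deterministic: rerunning the same config yields
#' byte-identical files.
#'
#' @param config list (see [read_run_config()]) or path to a config file.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    cfg_path <- config
    config <- read_run_config(config)
  } else {
    config <- .validate_config(config)
    cfg_path <- NULL
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  corp <- .stage("read_corpus", read_corpus(config$corpus))
  counts <- list(posts_read = nrow(corp$posts), users_read = nrow(corp$users))

  kw <- .stage("keywords", load_keyword_list(config$keywords))
  filt <- .stage("relevance_filter", filter_corpus(corp$posts, kw))
  posts <- filt$kept
  counts$posts_relevant <- nrow(posts)

  first_tab <- if (!is.null(config$names_first)) load_name_table(config$names_first)
  last_tab <- if (!is.null(config$names_last)) load_name_table(config$names_last)
  users <- .stage("demographics",
                  infer_demographics(posts, corp$users, first_tab, last_tab,
                                     config$gender_dominance,
                                     config$ethnicity_dominance))

  sent_lex <- .stage("sentiment_lexicon",
                     load_sentiment_lexicon(config$sentiment_lexicon))
  emo_lex <- .stage("emotion_lexicon",
                    load_emotion_lexicon(config$emotion_lexicon))
  scores <- .stage("scoring", score_posts(posts, sent_lex, emo_lex))
  counts$posts_scored <- sum(scores$n_matched > 0L)

  dict <- .stage("concept_dictionary", load_concept_dictionary(config$concepts))
  bl <- .stage("blacklist", load_blacklist(config$blacklist))
  ann <- .stage("annotation", annotate_posts(posts, dict, bl))
  counts$posts_annotated <- length(unique(ann$post_id))
  counts$concept_occurrences <- nrow(ann)

  terms <- term_stream(posts)
  allow <- if (!is.null(config$display_allow)) .read_word_file(config$display_allow)
  block <- if (!is.null(config$display_block)) .read_word_file(config$display_block)

  group_sizes <- list()
  for (attr in config$attributes) {
    parts <- partition_posts(posts, users, attr)
    if (length(parts) < 2L) {
      warning("attribute '", attr, "' has fewer than 2 annotated groups; skipped")
      next
    }
    group_sizes[[attr]] <- vapply(parts, nrow, integer(1))

    streams <- list(
      terms = terms,
      disorders = concept_stream(ann, "Disorders"),
      drugs = concept_stream(ann, "Chemicals & Drugs")
    )
    for (nm in names(streams)) {
      st <- streams[[nm]]
      if (nrow(st) == 0L) next
      ft <- build_freq_table(parts, st, drop_stopwords = (nm == "terms"))
      rd <- relative_differences(ft)
      top <- top_distinctive(rd, k = config$k, min_reldif = config$min_reldif,
                             allow = if (nm == "terms") allow,
                             block = if (nm == "terms") block)
      .write_tsv(top, file.path(config$out_dir,
                                paste0(attr, "_", nm, ".tsv")))
    }

    agg <- aggregate_groups(scores, posts, users, attr, alpha = config$alpha)
    .write_tsv(agg$sentiment, file.path(config$out_dir,
                                        paste0(attr, "_sentiment.tsv")))
    .write_tsv(agg$emotions, file.path(config$out_dir,
                                       paste0(attr, "_emotions.tsv")))
    .write_tsv(report_emotion_table(agg$emotions),
               file.path(config$out_dir, paste0(attr, "_emotion_table.tsv")))
  }

  cfg_hash <- {
    tmp <- tempfile()
    on.exit(unlink(tmp), add = TRUE)
    writeLines(jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE),
               tmp)
    unname(tools::md5sum(tmp))
  }
  manifest <- list(config_hash = cfg_hash, seed = config$seed,
                   counts = counts, group_sizes = group_sizes)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Build a self-contained demo run
#'
#' Writes fixture lexicons and a synthetic corpus under `dir` and returns a
#' ready-to-run pipeline config pointing at them — used by the bundled
#' analysis scripts and the validation suite.
#'
#' @param dir working directory for inputs and outputs.
#' @param seed generator seed.
#' @param posts_per_group corpus size per group.
#' @return config list for [run_pipeline()].
#' @export
demo_config <- function(dir, seed = 1L, posts_per_group = 1000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- generate_fixture_lexicons(file.path(dir, "fixtures"), seed = seed)
  cfg <- generator_config(seed = seed, posts_per_group = posts_per_group)
  corp <- generate_corpus(cfg)
  stem <- file.path(dir, "corpus")
  write_corpus(corp$posts, corp$users, stem)
  list(corpus = stem,
       sentiment_lexicon = unname(paths["sentiment"]),
       emotion_lexicon = unname(paths["emotion"]),
       concepts = unname(paths["concepts"]),
       blacklist = unname(paths["blacklist"]),
       keywords = unname(paths["keywords"]),
       names_first = unname(paths["names_first"]),
       names_last = unname(paths["names_last"]),
       attributes = "gender",
       out_dir = file.path(dir, "reports"),
       seed = seed)
}
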
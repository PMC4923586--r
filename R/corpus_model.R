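# Core corpus data model: posts and user profiles as tibbles, JSON-lines I/O,
# demographic binning, per-attribute partitioning.

.post_cols <- c("post_id", "user_id", "text", "source", "timestamp")
.user_cols <- c("user_id", "first_name", "last_name", "gender", "age_years",
                "location_state", "region", "ethnicity", "writing_level_grade",
                "gender_provenance", "ethnicity_provenance",
                "writing_level_provenance")

.sources <- c("social_network", "drug_review", "forum")
.genders <- c("male", "female")
.ethnicities <- c("white", "black", "asian", "hispanic")
.regions <- c("Northeast", "Midwest", "South", "West")
.age_labels <- c("0-17", "18-34", "35-44", "45-64", "65+")
.wl_labels <- c("0-5", "6-9", "10-16")
.attributes <- c("gender", "age_group", "ethnicity", "region", "writing_level_bin")

#' Construct a post table
#'
#' @param post_id,user_id,text character vectors of equal length.
#' @param source post origin, one of `social_network`, `drug_review`, `forum`.
#' @param timestamp optional ISO-8601 strings.
#' @return tibble with one row per post.
#' @export
posts_tibble <- function(post_id, user_id, text, source = "social_network",
                         timestamp = NA_character_) {
  n <- length(post_id)
  user_id <- rep_len(as.character(user_id), n)
  source <- rep_len(source, n)
  timestamp <- rep_len(timestamp, n)
  stopifnot(length(text) == n, all(source %in% .sources))
  if (any(!nzchar(trimws(text)))) stop("post text must be non-empty")
  if (anyDuplicated(post_id)) {
    dup <- unique(post_id[duplicated(post_id)])
    stop("duplicate post_id: ", paste(utils::head(dup, 5), collapse = ", "))
  }
  tibble::tibble(post_id = as.character(post_id), user_id = as.character(user_id),
                 text = text, source = source, timestamp = timestamp)
}

#' Construct a user-profile table
#'
#' All demographic fields are optional (`NA` = missing). Provenance columns
#' record whether gender / ethnicity / writing level were `reported` in the
#' input, `classified` by [infer_demographics()], or are `missing`.
#'
#' @param user_id character vector.
#' @param first_name,last_name,gender,age_years,location_state,region,ethnicity,writing_level_grade
#'   optional per-user attributes, recycled to length of `user_id`.
#' @return tibble with one row per user.
#' @export
users_tibble <- function(user_id, first_name = NA_character_,
                         last_name = NA_character_, gender = NA_character_,
                         age_years = NA_integer_, location_state = NA_character_,
                         region = NA_character_, ethnicity = NA_character_,
                         writing_level_grade = NA_real_) {
  n <- length(user_id)
  u <- tibble::tibble(
    user_id = as.character(user_id),
    first_name = rep_len(as.character(first_name), n),
    last_name = rep_len(as.character(last_name), n),
    gender = rep_len(as.character(gender), n),
    age_years = rep_len(as.integer(age_years), n),
    location_state = rep_len(as.character(location_state), n),
    region = rep_len(as.character(region), n),
    ethnicity = rep_len(as.character(ethnicity), n),
    writing_level_grade = rep_len(as.numeric(writing_level_grade), n)
  )
  if (anyDuplicated(u$user_id)) stop("duplicate user_id")
  stopifnot(all(is.na(u$gender) | u$gender %in% .genders),
            all(is.na(u$ethnicity) | u$ethnicity %in% .ethnicities),
            all(is.na(u$age_years) | u$age_years >= 0L),
            all(is.na(u$writing_level_grade) | u$writing_level_grade >= 0))
  u$gender_provenance <- ifelse(is.na(u$gender), "missing", "reported")
  u$ethnicity_provenance <- ifelse(is.na(u$ethnicity), "missing", "reported")
  u$writing_level_provenance <- ifelse(is.na(u$writing_level_grade), "missing", "reported")
  u
}

.jsonl_write <- function(df, path) {
  lines <- vapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, , drop = FALSE])
    rec <- rec[!vapply(rec, function(v) is.na(v[[1]]), logical(1))]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
}

#' Write a corpus as JSON-lines
#'
#' Posts go to `<stem>.posts.jsonl`, users to `<stem>.users.jsonl` — one JSON
#' record per line, absent optional fields omitted from the record.
#'
#' @param posts,users tibbles from [posts_tibble()] / [users_tibble()].
#' @param stem path prefix for the two files.
#' @return invisibly, the two file paths.
#' @export
write_corpus <- function(posts, users, stem) {
  pp <- paste0(stem, ".posts.jsonl")
  up <- paste0(stem, ".users.jsonl")
  .jsonl_write(posts, pp)
  u <- users[, setdiff(names(users), grep("_provenance$", names(users), value = TRUE))]
  names(u)[names(u) == "age_years"] <- "age"
  names(u)[names(u) == "location_state"] <- "state"
  .jsonl_write(u, up)
  invisible(c(posts = pp, users = up))
}

.jsonl_read <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  bad <- 0L
  for (i in seq_along(lines)) {
    r <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) NULL)
    if (is.null(r) || is.null(names(r))) bad <- bad + 1L else recs[[i]] <- r
  }
  list(records = recs[!vapply(recs, is.null, logical(1))], n_malformed = bad,
       n_lines = length(lines))
}

.field <- function(recs, name, cast) {
  cast(vapply(recs, function(r) {
    v <- r[[name]]
    if (is.null(v) || length(v) == 0L) NA_character_ else as.character(v)
  }, character(1)))
}

#' Read a JSON-lines corpus
#'
#' Expects the two files written by [write_corpus()]. Malformed lines are
#' counted and reported via warning rather than aborting, unless more than
#' half of a file fails to parse.
#'
#' @param stem path prefix (reads `<stem>.posts.jsonl`, `<stem>.users.jsonl`).
#' @return list with `posts`, `users`, and `n_malformed`.
#' @export
read_corpus <- function(stem) {
  pp <- paste0(stem, ".posts.jsonl")
  up <- paste0(stem, ".users.jsonl")
  for (f in c(pp, up)) if (!file.exists(f)) stop("corpus file not found: ", f)
  pr <- .jsonl_read(pp)
  ur <- .jsonl_read(up)
  for (x in list(pr, ur)) {
    if (x$n_lines > 0L && x$n_malformed > x$n_lines / 2)
      stop("more than half of corpus lines are malformed")
  }
  if (length(pr$records) == 0L) stop("empty corpus: no posts in ", pp)
  posts <- posts_tibble(
    post_id = .field(pr$records, "post_id", identity),
    user_id = .field(pr$records, "user_id", identity),
    text = .field(pr$records, "text", identity),
    source = {
      s <- .field(pr$records, "source", identity)
      ifelse(is.na(s), "social_network", s)
    },
    timestamp = .field(pr$records, "timestamp", identity)
  )
  users <- users_tibble(
    user_id = .field(ur$records, "user_id", identity),
    first_name = .field(ur$records, "first_name", identity),
    last_name = .field(ur$records, "last_name", identity),
    gender = .field(ur$records, "gender", identity),
    age_years = .field(ur$records, "age", as.integer),
    location_state = .field(ur$records, "state", identity),
    region = .field(ur$records, "region", identity),
    ethnicity = .field(ur$records, "ethnicity", identity),
    writing_level_grade = .field(ur$records, "writing_level_grade", as.numeric)
  )
  nm <- pr$n_malformed + ur$n_malformed
  if (nm > 0L) warning(nm, " malformed corpus line(s) skipped")
  list(posts = posts, users = users, n_malformed = nm)
}

#' Assign ages to the study's age groups
#'
#' Closed integer bins: 0-17, 18-34, 35-44, 45-64, 65+.
#'
#' @param age_years integer vector, each >= 0.
#' @return character vector of bin labels.
#' @examples bin_age(c(17, 18, 34, 35, 64, 65))
#' @export
bin_age <- function(age_years) {
  stopifnot(all(is.na(age_years) | age_years >= 0))
  cut(as.integer(age_years), breaks = c(-1L, 17L, 34L, 44L, 64L, Inf),
      labels = .age_labels) |> as.character()
}

#' Assign a writing-level grade to its reporting bin
#'
#' Edges: grades in \[0,6) map to `0-5`, \[6,10) to `6-9`, \[10,16\] to `10-16`.
#' Grades are produced clamped to \[0,16\] by [grade_text()].
#'
#' @param grade numeric vector of clamped grades.
#' @return character vector of bin labels.
#' @export
bin_writing_level <- function(grade) {
  stopifnot(all(is.na(grade) | (grade >= 0 & grade <= 16)))
  out <- rep(NA_character_, length(grade))
  out[!is.na(grade) & grade < 6] <- "0-5"
  out[!is.na(grade) & grade >= 6 & grade < 10] <- "6-9"
  out[!is.na(grade) & grade >= 10] <- "10-16"
  out
}

# US Census Bureau four-region assignment (50 states + DC)
.census_region <- c(
  CT = "Northeast", ME = "Northeast", MA = "Northeast", NH = "Northeast",
  RI = "Northeast", VT = "Northeast", NJ = "Northeast", NY = "Northeast",
  PA = "Northeast",
  IL = "Midwest", IN = "Midwest", MI = "Midwest", OH = "Midwest", WI = "Midwest",
  IA = "Midwest", KS = "Midwest", MN = "Midwest", MO = "Midwest", NE = "Midwest",
  ND = "Midwest", SD = "Midwest",
  DE = "South", FL = "South", GA = "South", MD = "South", NC = "South",
  SC = "South", VA = "South", DC = "South", WV = "South", AL = "South",
  KY = "South", MS = "South", TN = "South", AR = "South", LA = "South",
  OK = "South", TX = "South",
  AZ = "West", CO = "West", ID = "West", MT = "West", NV = "West", NM = "West",
  UT = "West", WY = "West", AK = "West", CA = "West", HI = "West", OR = "West",
  WA = "West"
)

#' Map US state codes to Census regions
#'
#' Standard US Census Bureau four-region table (Northeast, Midwest, South,
#' West; DC counted in the South). Unknown codes yield `NA` with a warning.
#'
#' @param location_state character vector of 2-letter codes.
#' @return character vector of region names.
#' @examples map_region(c("NY", "CA", "TX"))
#' @export
map_region <- function(location_state) {
  code <- toupper(location_state)
  out <- unname(.census_region[code])
  unknown <- !is.na(location_state) & is.na(out)
  if (any(unknown))
    warning("unknown state code(s): ",
            paste(unique(code[unknown]), collapse = ", "))
  out
}

# Resolve the per-user value of a partition attribute (derived bins included).
.attribute_values <- function(users, attribute) {
  switch(attribute,
    gender = users$gender,
    age_group = bin_age(users$age_years),
    ethnicity = users$ethnicity,
    region = ifelse(!is.na(users$region), users$region,
                    suppressWarnings(map_region(users$location_state))),
    writing_level_bin = bin_writing_level(users$writing_level_grade),
    stop("unknown attribute: ", attribute)
  )
}

#' Partition posts by a demographic attribute
#'
#' Posts whose author lacks the attribute are excluded (the per-attribute
#' denominator is posts by users annotated for that attribute, not the whole
#' corpus). Parts are disjoint and cover exactly the annotated posts.
#'
#' @param posts,users corpus tibbles.
#' @param attribute one of `gender`, `age_group`, `ethnicity`, `region`,
#'   `writing_level_bin`.
#' @return named list: attribute value -> tibble of posts.
#' @export
partition_posts <- function(posts, users, attribute) {
  attribute <- match.arg(attribute, .attributes)
  vals <- .attribute_values(users, attribute)
  names(vals) <- users$user_id
  pv <- vals[posts$user_id]
  keep <- !is.na(pv)
  if (!any(keep)) {
    warning("no posts annotated for attribute '", attribute, "'")
    return(structure(list(), names = character(0)))
  }
  split(posts[keep, , drop = FALSE], pv[keep])
}
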
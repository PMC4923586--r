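first_tab <- load_name_table(extdata("names_first.tsv"))
last_tab <- load_name_table(extdata("names_last.tsv"))

test_that("name classifiers apply the dominance rule case-insensitively", {
  # mary: shares (female .996, male .004) -> female
  expect_equal(classify_gender(c("mary", "MARY", "Mary"), first_tab),
               rep("female", 3))
  # jordan: (.55, .45) sits below dominance -> unknown
  expect_equal(classify_gender("jordan", first_tab), "unknown")
  expect_equal(classify_gender("notintable", first_tab), "unknown")
  expect_equal(classify_gender(NA_character_, first_tab), "unknown")

  expect_equal(classify_ethnicity("Garcia", last_tab), "hispanic")  # share .93
  expect_equal(classify_ethnicity("lee", last_tab), "unknown")      # max .45
  expect_equal(classify_ethnicity("", last_tab), "unknown")

  # dominance 1.0 labels only unanimous names
  expect_equal(classify_gender("mary", first_tab, dominance = 1.0), "unknown")
  # threshold is inclusive
  expect_equal(classify_ethnicity("garcia", last_tab, dominance = 0.93), "hispanic")
})

test_that("name tables must have shares summing to one", {
  f <- write_temp_lexicon(c("pat\tmale\t0.5", "pat\tfemale\t0.4"))
  expect_error(load_name_table(f), "sum to 1")
})

test_that("grade_text reproduces hand-computed Flesch-Kincaid values", {
  # 6 words, 1 sentence, 6 syllables: .39*6 + 11.8*1 - 15.59 = -1.45 -> 0
  expect_equal(grade_text("The cat sat on the mat."), 0)
  # 20 words, 1 sentence, 30 syllables: .39*20 + 11.8*1.5 - 15.59 = 9.91
  s20 <- paste("The dog ran fast down the long road with his doctor after",
               "morning under yellow summer winter garden window river.")
  expect_equal(grade_text(s20), 9.91, tolerance = 1e-2)
  # no terminal punctuation counts as one sentence; heavy polysyllables clamp at 16
  expect_equal(grade_text("banana banana"), 16)
  expect_true(is.na(grade_text("")))
  expect_true(is.na(grade_text("...")))
})

test_that("appending a polysyllabic word never lowers a one-sentence grade", {
  base <- "I took my meds today"
  g <- grade_text(base)
  for (i in 1:5) {
    base <- paste(base, "unbelievable")
    g2 <- grade_text(base)
    expect_gte(g2, g)
    g <- g2
  }
})

test_that("user writing level averages per-post grades and bins per the edges", {
  wl <- user_writing_level(c("The cat sat on the mat.", s20 <- paste(
    "The dog ran fast down the long road with his doctor after",
    "morning under yellow summer winter garden window river.")))
  expect_equal(wl$n_posts_used, 2L)
  expect_equal(wl$grade, mean(c(0, 9.91)), tolerance = 1e-2)
  expect_equal(wl$bin, "0-5")

  expect_equal(bin_writing_level(c(0, 5.99, 6, 9.99, 10, 16)),
               c("0-5", "0-5", "6-9", "6-9", "10-16", "10-16"))
  # bins partition [0,16]
  g <- seq(0, 16, by = 0.25)
  b <- bin_writing_level(g)
  expect_false(any(is.na(b)))
  expect_setequal(unique(b), c("0-5", "6-9", "10-16"))

  none <- user_writing_level(c("", "..."))
  expect_true(is.na(none$grade))
  expect_equal(none$n_posts_used, 0L)
})

test_that("infer_demographics fills gaps, marks provenance, keeps reported values", {
  corp <- tiny_corpus()
  u <- infer_demographics(corp$posts, corp$users, first_tab, last_tab)
  # u7 (John, gender missing) gets classified male
  expect_equal(u$gender[u$user_id == "u7"], "male")
  expect_equal(u$gender_provenance[u$user_id == "u7"], "classified")
  # u8 (Jordan) stays missing: ambiguous name
  expect_true(is.na(u$gender[u$user_id == "u8"]))
  # reported values untouched
  expect_equal(u$gender[u$user_id == "u1"], "female")
  expect_equal(u$gender_provenance[u$user_id == "u1"], "reported")
  # writing level computed from the user's posts
  expect_false(any(is.na(u$writing_level_grade[u$user_id %in% corp$posts$user_id])))
  expect_true(all(u$writing_level_provenance[u$user_id %in% corp$posts$user_id]
                  == "classified"))
})
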
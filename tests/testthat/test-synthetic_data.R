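test_that("manifest carries the closed-form expected relative differences", {
  pt <- tibble::tibble(term = "planted01", target_group = "male",
                       rate_in_target = 0.03, rate_elsewhere = 0.01)
  cfg <- generator_config(seed = 1, posts_per_group = 10L, planted_terms = pt)
  man <- generate_corpus(cfg)$manifest
  # rates (.03, .01): mean .02 -> +0.5 target, -0.5 other
  expect_equal(man$planted$expected_rel_dif[man$planted$group == "male"], 0.5)
  expect_equal(man$planted$expected_rel_dif[man$planted$group == "female"], -0.5)

  # identical rates -> all zero
  pt0 <- tibble::tibble(term = "planted01", target_group = "male",
                        rate_in_target = 0.02, rate_elsewhere = 0.02)
  man0 <- generate_corpus(generator_config(seed = 1, posts_per_group = 10L,
                                           planted_terms = pt0))$manifest
  expect_true(all(man0$planted$expected_rel_dif == 0))
})

test_that("expected relative differences sum to zero across groups per term", {
  cfg <- generator_config(seed = 2, posts_per_group = 10L)
  man <- generate_corpus(cfg)$manifest
  sums <- tapply(man$planted$expected_rel_dif, man$planted$term, sum)
  expect_true(all(abs(sums) < 1e-12))
})

test_that("a fixed seed reproduces the corpus byte-for-byte", {
  a <- generate_corpus(generator_config(seed = 99, posts_per_group = 30L))
  b <- generate_corpus(generator_config(seed = 99, posts_per_group = 30L))
  expect_identical(a$posts, b$posts)
  expect_identical(a$users, b$users)
  c2 <- generate_corpus(generator_config(seed = 100, posts_per_group = 30L))
  expect_false(identical(a$posts$text, c2$posts$text))
})

test_that("degenerate configurations are rejected", {
  expect_error(generator_config(seed = 1, groups = character(0)), "at least one group")
  expect_error(generator_config(seed = 1, posts_per_group = 0L), "at least one post")
  expect_error(generator_config(
    seed = 1,
    planted_terms = tibble::tibble(term = "x", target_group = "male",
                                   rate_in_target = 0.01, rate_elsewhere = 0.05)))
})

test_that("planted-term frequency converges to the configured rate", {
  cfg <- generator_config(seed = 5, posts_per_group = 10000L)
  corp <- generate_corpus(cfg)
  male_users <- corp$users$user_id[!is.na(corp$users$gender) &
                                     corp$users$gender == "male"]
  txt <- corp$posts$text[corp$posts$user_id %in% male_users]
  toks <- unlist(strsplit(txt, " ", fixed = TRUE))
  # injected emotion suffix tokens dilute the per-token rate; measure on the
  # multinomial draw only
  toks <- toks[!toks %in% unlist(demotext:::.gen_emotion_pools)]
  r_hat <- mean(toks == "planted01")
  r <- 0.03
  se <- sqrt(r * (1 - r) / length(toks))
  expect_lt(abs(r_hat - r), 3 * se)
})

test_that("fixture lexicons satisfy their structural contracts", {
  d <- tempfile()
  paths <- generate_fixture_lexicons(d, seed = 7)
  # every sentiment row sums to one after deriving the objective score
  raw <- readLines(paths[["sentiment"]])
  raw <- raw[!startsWith(raw, "#")]
  f <- do.call(rbind, strsplit(raw, "\t"))
  expect_true(all(abs(as.numeric(f[, 3]) + as.numeric(f[, 4]) +
                        (1 - as.numeric(f[, 3]) - as.numeric(f[, 4])) - 1) < 1e-9))
  # dictionary holds a two-token synonym and the blacklisted surface form
  conc <- readLines(paths[["concepts"]])
  expect_true(any(grepl("heart attack", conc, fixed = TRUE)))
  bl <- read.delim(paths[["blacklist"]], header = FALSE)
  expect_true("i" %in% bl$V1)
  ip <- bl$V2[bl$V1 == "i"]
  expect_true(any(grepl(paste0("^", ip, "\t.*[Ii]mmunologic"), conc)))
})
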
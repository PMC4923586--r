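test_that("minimum occurrence threshold is max(0.0001 n, 30)", {
  expect_equal(min_occurrence_threshold(1e6), 100)
  expect_equal(min_occurrence_threshold(50000), 30)   # 5 < 30, floor applies
  expect_equal(min_occurrence_threshold(300000), 30)  # boundary: exactly 30
  expect_equal(min_occurrence_threshold(0), 30)
})

test_that("frequency table implements occurrences / group posts with thresholding", {
  # 10 occurrences in 200 posts -> freq 0.05; groups below 2 rejected
  parts <- list(
    male = posts_tibble(sprintf("m%d", 1:200), "u1",
                        c(rep("headache pounding", 10), rep("bkg0001 filler", 190)),
                        source = "forum"),
    female = posts_tibble(sprintf("f%d", 1:200), "u2",
                          rep("bkg0002 filler", 200), source = "forum")
  )
  ts <- term_stream(rbind(parts$male, parts$female))
  ft <- build_freq_table(parts, ts)
  # n = 400 posts -> threshold 30; "headach" has 10 occurrences -> dropped
  expect_false("headach" %in% ft$freq$item)
  expect_equal(ft$threshold, 30)
  # "filler" occurs 390 times -> kept, freq per group = count/posts
  expect_equal(ft$freq$freq[ft$freq$item == "filler" & ft$freq$group == "male"],
               190 / 200)
  expect_error(build_freq_table(parts["male"], ts), "at least 2 groups")
})

test_that("relative differences follow the two-group and four-group arithmetic", {
  # hand case: freqs (male .06, female .02) -> avg .04 -> +/- 0.5
  ft <- list(freq = tibble::tibble(item = "headach", group = c("male", "female"),
                                   n_occurrences = c(6L, 2L), freq = c(0.06, 0.02)),
             n_posts = c(male = 100L, female = 100L), threshold = 30, n_annotated = 200L)
  rd <- relative_differences(ft)
  expect_equal(rd$avg_freq, rep(0.04, 2))
  expect_equal(sort(rd$rel_dif), c(-0.5, 0.5))

  # four groups (.02,.02,.02,.10) -> (-.5,-.5,-.5,+1.5), sum zero
  ft4 <- list(freq = tibble::tibble(item = "x", group = c("NE", "MW", "S", "W"),
                                    n_occurrences = 1:4,
                                    freq = c(0.02, 0.02, 0.02, 0.10)),
              n_posts = c(NE = 1L, MW = 1L, S = 1L, W = 1L), threshold = 30,
              n_annotated = 4L)
  rd4 <- relative_differences(ft4)
  expect_equal(sort(rd4$rel_dif), c(-0.5, -0.5, -0.5, 1.5))
  expect_equal(sum(rd4$rel_dif), 0)

  # equal frequencies -> all zero
  ft0 <- ft; ft0$freq$freq <- c(0.05, 0.05)
  expect_true(all(relative_differences(ft0)$rel_dif == 0))
})

test_that("relative differences sum to zero and are antisymmetric for two groups", {
  cfg <- generator_config(seed = 41, posts_per_group = 300L)
  corp <- generate_corpus(cfg)
  parts <- partition_posts(corp$posts, corp$users, "gender")
  rd <- relative_differences(build_freq_table(parts, term_stream(corp$posts)))
  sums <- tapply(rd$rel_dif, rd$item, sum)
  expect_true(all(abs(sums) < 1e-9))
  wide <- split(rd$rel_dif, rd$group)
  ord <- split(rd$item, rd$group)
  expect_equal(ord$male, ord$female)
  expect_equal(wide$male, -wide$female)
  expect_true(all(rd$rel_dif > -1))
  expect_true(all(rd$avg_freq > 0))
})

test_that("duplicating every post leaves relative differences unchanged", {
  cfg <- generator_config(seed = 42, posts_per_group = 150L)
  corp <- generate_corpus(cfg)
  parts <- partition_posts(corp$posts, corp$users, "gender")
  rd1 <- relative_differences(build_freq_table(parts, term_stream(corp$posts)))

  dup_posts <- corp$posts
  dup_posts$post_id <- paste0(dup_posts$post_id, "dup")
  both <- rbind(corp$posts, dup_posts)
  parts2 <- partition_posts(both, corp$users, "gender")
  rd2 <- relative_differences(build_freq_table(parts2, term_stream(both)))

  common <- intersect(unique(rd1$item), unique(rd2$item))
  expect_setequal(unique(rd1$item), common)  # doubling can only add items
  m1 <- rd1[rd1$item %in% common, ]
  m2 <- rd2[rd2$item %in% common, ]
  m2 <- m2[match(paste(m1$item, m1$group), paste(m2$item, m2$group)), ]
  expect_equal(m1$rel_dif, m2$rel_dif)
  expect_equal(m1$freq, m2$freq)
})

test_that("top lists rank by relative difference with documented tie-breaks", {
  rd <- tibble::tibble(
    item = c("a", "b", "c", "d", "e", "e"),
    group = c("g1", "g1", "g1", "g1", "g1", "g2"),
    freq = c(1, 1, 1, 1, 1, 1),
    avg_freq = c(0.5, 0.9, 0.5, 0.5, 0.2, 0.2),
    rel_dif = c(0.5, 0.3, 0.3, 0.05, 0.3, -0.3)
  )
  top <- top_distinctive(rd, k = 10)
  g1 <- top[top$group == "g1", ]
  # a first (largest), then b (tie on 0.3 broken by avg_freq), then c, then e
  expect_equal(g1$item, c("a", "b", "c", "e"))
  expect_equal(g1$rank, 1:4)
  # d below the 0.1 display threshold; g2's only item negative -> absent group
  expect_false("d" %in% top$item)
  expect_false("g2" %in% top$group)
  # k truncates; k = 1 returns the argmax
  expect_equal(top_distinctive(rd, k = 1)$item, "a")
  # display filter applies before truncation
  expect_equal(top_distinctive(rd, k = 1, block = "a")$item, "b")
  expect_equal(top_distinctive(rd, k = 1, allow = c("c", "d"))$item, "c")
})

test_that("full chain matches the brute-force recount oracle exactly", {
  cfg <- generator_config(seed = 43, posts_per_group = 100L)
  corp <- generate_corpus(cfg)
  parts <- partition_posts(corp$posts, corp$users, "gender")
  rd <- relative_differences(build_freq_table(parts, term_stream(corp$posts)))
  orac <- oracle_distinctive(parts)
  key <- function(d) paste(d$item, d$group)
  expect_setequal(key(rd), key(orac))
  m <- match(key(orac), key(rd))
  expect_equal(rd$freq[m], orac$freq, tolerance = 1e-12)
  expect_equal(rd$rel_dif[m], orac$rel_dif, tolerance = 1e-12)
  expect_equal(rd$avg_freq[m], orac$avg_freq, tolerance = 1e-12)
})
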
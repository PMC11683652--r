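pat <- stroke_legacy_pattern()

test_that("find_candidates matches variants at word boundaries, one per variant", {
  f <- quick_forum(
    list("A", "B", "C", "D"),
    texts = list("fatigue is a stroke legacy",
                 "I felt tired today",
                 "my Legacy my legacy twice but one hit and legacies too",
                 "delegacy is not a hit")
  )
  cand <- find_candidates(f, pat)
  expect_equal(cand$variant[cand$author == "A"], "legacy")
  expect_false("B" %in% cand$author)
  # repeated variant in one post counts once; distinct variants separately
  expect_setequal(cand$variant[cand$author == "C"], c("legacy", "legacies"))
  # no substring matches inside words
  expect_false("D" %in% cand$author)
  expect_equal(cand$post_index, sort(cand$post_index))
})

test_that("planted phrase posts are recovered exactly (naive scan oracle)", {
  sf <- generate_forum(small_config(seed = 21))
  cand <- find_candidates(sf$forum, sf$pattern)
  oracle_hits <- grepl("\\blegac(y|ies)\\b", tolower(sf$forum$posts$text))
  expect_equal(sort(cand$post_index), sf$forum$posts$post_index[oracle_hits])
  expect_equal(nrow(cand), nrow(sf$truth$phrase_posts))
})

test_that("adding variants never removes candidates (monotonicity)", {
  fx <- narrative_forum()
  base <- phrase_pattern("legacy of stroke", keywords = "legacy")
  wider <- phrase_pattern("legacy of stroke",
                          keywords = c("legacy", "legacies"),
                          synonyms = c("heritage", "footprint"))
  c1 <- find_candidates(fx$forum, base)
  c2 <- find_candidates(fx$forum, wider)
  key <- function(d) paste(d$post_index, d$variant)
  expect_true(all(key(c1) %in% key(c2)))
})

test_that("context rule: same-post and windowed confirmation", {
  f <- quick_forum(
    list("A", "B", "C"),
    texts = list("the legacy of stroke lives on",
                 "my grandmother's legacy was a garden",
                 paste("legacy first", paste(rep("word", 10), collapse = " "),
                       "stroke much later"))
  )
  cand <- find_candidates(f, pat)
  same_post <- apply_context_rule(cand, pat, f)
  expect_equal(same_post$status[same_post$author == "A"], "confirmed")
  expect_equal(same_post$status[same_post$author == "B"], "candidate")
  expect_equal(same_post$status[same_post$author == "C"], "confirmed")

  narrow <- phrase_pattern("legacy of stroke", keywords = c("legacy"),
                           context_terms = c("stroke"), context_window = 3L)
  windowed <- apply_context_rule(find_candidates(f, narrow), narrow, f)
  expect_equal(windowed$status[windowed$author == "A"], "confirmed")
  expect_equal(windowed$status[windowed$author == "C"], "candidate")
})

test_that("merge_annotations overrides the rule and validates references", {
  f <- quick_forum(
    list("A", "B"),
    texts = list("legacy of stroke", "legacy of my aunt")
  )
  m <- apply_context_rule(find_candidates(f, pat), pat, f)
  # empty annotations: unchanged
  expect_identical(merge_annotations(m, NULL), m)

  ann <- data.frame(post_index = c(1L, 2L),
                    decision = c("reject", "confirm"),
                    topic = c(NA, "other"))
  out <- merge_annotations(m, ann)
  expect_equal(out$status, c("rejected", "confirmed"))
  expect_equal(out$topic[2], "other")

  bad <- data.frame(post_index = 99L, decision = "confirm", topic = "other")
  expect_error(merge_annotations(m, bad), "no candidate mention")
})

test_that("random annotation tables obey set algebra (oracle check)", {
  sf <- generate_forum(small_config(seed = 33))
  m <- apply_context_rule(find_candidates(sf$forum, sf$pattern),
                          sf$pattern, sf$forum)
  expect_gte(nrow(m), 4L)
  set.seed(101)
  for (rep in 1:5) {
    pick <- sample(m$post_index, size = ceiling(nrow(m) / 2))
    dec <- sample(c("confirm", "reject"), length(pick), replace = TRUE)
    ann <- data.frame(post_index = pick, decision = dec, topic = "other")
    out <- merge_annotations(m, ann)
    # oracle: confirmed-by-rule minus rejected plus annotation-confirmed
    expected <- union(
      setdiff(m$post_index[m$status == "confirmed"], pick[dec == "reject"]),
      pick[dec == "confirm"]
    )
    expect_setequal(confirmed_mentions(out)$post_index, expected)
  }
})

test_that("topic percentages round half-up and cover the 34/61 split", {
  m <- data.frame(
    post_index = 1:61, thread_id = "t", author = "a", variant = "legacy",
    status = "confirmed",
    topic = rep(c("fatigue", "other"), c(34L, 27L))
  )
  pct <- topic_percentages(m)
  expect_equal(pct[["fatigue"]], 56L)
  expect_equal(pct[["other"]], 44L)
  expect_equal(sum(pct), 100L)
  expect_equal(round_half_up(c(0.5, 1.5, -0.5, 55.738)), c(1, 2, -1, 56))
})

test_that("corpus_frequency counts exact normalized strings", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("nothing to see here", "plain words only"), f1)
  writeLines(c("Fatigue is a   legacy of stroke.",
               "again: fatigue is a legacy of stroke"), f2)
  q <- c("fatigue is a legacy of stroke", "tiredness is a legacy of stroke")

  res1 <- corpus_frequency(f1, q)
  expect_true(res1$novel)
  expect_equal(unname(res1$counts), c(0L, 0L))

  res2 <- corpus_frequency(c(f1, f2), q)
  expect_false(res2$novel)
  expect_equal(unname(res2$counts[1]), 2L)

  # corpus equal to the query string itself
  f3 <- tempfile(); writeLines(q[1], f3)
  expect_equal(unname(corpus_frequency(f3, q[1])$counts), 1L)

  # planted n copies
  f4 <- tempfile()
  writeLines(rep("well fatigue is a legacy of stroke indeed", 7), f4)
  expect_equal(unname(corpus_frequency(f4, q[1])$counts), 7L)

  expect_error(corpus_frequency("does-not-exist.txt", q), "not readable")
})
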
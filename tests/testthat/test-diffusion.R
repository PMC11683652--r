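# The narrative fixture and its inference, shared by most blocks here.
fx <- narrative_forum()
res <- infer_forum(fx$forum, fx$pattern, fx$annotations)

test_that("participation_timeline dedupes threads and orders by first post", {
  f <- quick_forum(list("A", c("B", "A"), "C", "A", c("A", "B")))
  # A posts in t002, t004, t005 (twice counted once each)... plus t001
  tl <- participation_timeline(f, "A")
  expect_equal(tl$thread_id, c("t001", "t002", "t004", "t005"))
  expect_false(anyDuplicated(tl$thread_id) > 0)
  expect_error(participation_timeline(f, "nobody"), "unknown user")

  # originator's first metaphor flag sits at thread number 2
  tlA <- participation_timeline(fx$forum, "A", res$mentions)
  first_flag <- tlA$thread_number[tlA$flag == "metaphor_by_user"][1]
  expect_equal(first_flag, 2L)

  # synthetic timelines match brute-force per-post grouping
  sf <- generate_forum(small_config(seed = 12))
  for (u in utils::head(sf$forum$users, 8)) {
    tl_u <- participation_timeline(sf$forum, u)
    rows <- sf$forum$posts[sf$forum$posts$author == u, ]
    oracle_first <- sort(tapply(rows$post_index, rows$thread_id, min))
    expect_equal(tl_u$thread_id, names(oracle_first))
    expect_equal(tl_u$first_post_index, unname(as.integer(oracle_first)))
  }
})

test_that("detect_adoptions yields one ordered event per author, root first", {
  ad <- res$adoptions
  expect_equal(nrow(ad), 8L)
  expect_equal(ad$user[1], "A")
  expect_equal(ad$first_use_thread[1], "t002")
  expect_true(all(diff(ad$first_use_post_index) > 0))
  # per-user metaphor threads are deduplicated
  expect_true(all(vapply(ad$metaphor_threads,
                         function(t) !anyDuplicated(t), logical(1))))

  one <- data.frame(post_index = 5L, thread_id = "t", author = "z",
                    variant = "legacy", status = "confirmed", topic = "other")
  ad1 <- detect_adoptions(one)
  expect_equal(ad1$user, "z")
  expect_equal(detect_adoptions(one[0, ])$user, character())

  # synthetic: adopter events equal the expressed planted adopters
  sf <- generate_forum(small_config(seed = 8, lurk_prob = 0))
  inf <- infer_synthetic(sf)
  planted <- sf$truth$adoptions[sf$truth$adoptions$expressed, "user"]
  expect_setequal(inf$adoptions$user, c(sf$truth$originator, planted))
  expect_equal(inf$adoptions$user[1], sf$truth$originator)
})

test_that("self_promotion_count counts distinct phrase threads per user", {
  counts <- self_promotion_count(res$adoptions)
  expect_equal(unname(counts["A"]), 51L)
  expect_equal(unname(counts["B"]), 2L)
  expect_equal(unname(counts["C"]), 1L)  # single-use adopter
  expect_error(self_promotion_count(res$adoptions, "nope"), "no adoption event")

  sf <- generate_forum(small_config(seed = 8, lurk_prob = 0))
  inf <- infer_synthetic(sf)
  orig_threads <- unique(sf$truth$phrase_posts$thread_id[
    sf$truth$phrase_posts$author == sf$truth$originator])
  expect_equal(unname(self_promotion_count(inf$adoptions, sf$truth$originator)),
               length(orig_threads))
})

test_that("classify_exposure assigns the narrative routes and sources", {
  ex <- res$exposures
  expect_equal(nrow(ex), 7L)
  direct <- ex[ex$route == "direct_metaphor_thread", ]
  expect_setequal(direct$adopter, c("B", "C", "F"))
  expect_true(all(direct$source == "A"))
  unrel <- ex[ex$route == "unrelated_co_thread", ]
  expect_setequal(unrel$adopter, c("D", "H"))
  expect_equal(unrel$source[unrel$adopter == "D"], "A")
  expect_equal(unrel$source[unrel$adopter == "H"], "B")
  lurk <- ex[ex$route == "lurking_presumed", ]
  expect_setequal(lurk$adopter, c("E", "G"))
  expect_true(all(is.na(lurk$source)))

  # consistency error when an adopter is missing from the forum
  ghost <- res$adoptions
  ghost$user[8] <- "phantom"
  expect_error(classify_exposure(fx$forum, res$mentions, ghost),
               "absent from forum")
})

test_that("removing the root's posts leaves no direct route sourced at the root", {
  pruned <- fx$forum$posts[fx$forum$posts$author != "A", , drop = FALSE]
  f2 <- as_forum(pruned)
  r2 <- infer_forum(f2, fx$pattern)
  direct <- r2$exposures[r2$exposures$route == "direct_metaphor_thread", ]
  expect_false(any(direct$source == "A"))
})

test_that("tree_depth matches the independent longest-path oracle", {
  chain <- data.frame(source = c("root", "x", "y"),
                      recipient = c("x", "y", "z"))
  expect_equal(tree_depth(chain, "root"), 3L)
  expect_equal(depth_oracle(chain, "root"), 3L)
  expect_equal(tree_depth(chain[0, ], "root"), 0L)

  cyc <- data.frame(source = c("root", "x"), recipient = c("x", "root"))
  expect_error(tree_depth(cyc, "root"), "cycle")

  for (seed in c(3, 14, 27)) {
    inf <- infer_synthetic(generate_forum(small_config(seed = seed)))
    expect_equal(inf$tree$depth, depth_oracle(inf$tree$edges, inf$tree$root))
  }
})

test_that("build_diffusion_tree assembles nodes, edges and depth", {
  tree <- res$tree
  expect_equal(tree$root, "A")
  expect_equal(nrow(tree$nodes), 68L)
  expect_equal(sum(tree$nodes$role == "adopter"), 8L)
  expect_equal(sum(tree$nodes$role == "recipient"), 60L)
  expect_equal(tree$depth, 3L)
  expect_equal(tree$depth, depth_oracle(tree$edges, tree$root))
  ad_edges <- tree$edges[tree$edges$kind == "adoption", ]
  expect_equal(nrow(ad_edges), 7L)  # one inbound adoption edge per non-root
  expect_false(anyDuplicated(ad_edges$recipient) > 0)
  # presumed lurkers attach to the root
  expect_true(all(ad_edges$source[ad_edges$mechanism == "lurking_presumed"] == "A"))
  # spreading edges are unique per (source, recipient) pair
  sp <- tree$edges[tree$edges$kind == "spreading_instance", ]
  expect_false(anyDuplicated(sp[, c("source", "recipient")]) > 0)

  # single-adopter forum: one node, depth 0
  solo <- quick_forum(list("Z"), texts = list("a legacy of stroke remains"))
  rs <- infer_forum(solo)
  expect_equal(nrow(rs$tree$nodes), 1L)
  expect_equal(rs$tree$depth, 0L)

  # empty mention set: empty tree
  empty <- infer_forum(quick_forum(list(c("A", "B"))))
  expect_equal(nrow(empty$tree$nodes), 0L)
  expect_equal(empty$tree$depth, 0L)
})

test_that("temporal consistency: every exposure precedes the adopter's first use", {
  for (seed in c(1, 6, 19)) {
    sf <- generate_forum(small_config(seed = seed, lurk_prob = 0.15))
    inf <- infer_synthetic(sf)
    fu <- stats::setNames(inf$adoptions$first_use_post_index,
                          inf$adoptions$user)
    ok <- is.na(inf$exposures$exposure_index) |
      inf$exposures$exposure_index < fu[inf$exposures$adopter]
    expect_true(all(ok))
  }
})

test_that("mechanism_summary aggregates routes, depth and superuser overlap", {
  ms <- mechanism_summary(res$tree, res$adoptions, profiles = fx$profiles)
  expect_equal(ms$n_nonroot_adopters, 7L)
  expect_equal(ms$n_superuser_nonroot_adopters, 3L)
  expect_equal(unname(ms$routes["direct_metaphor_thread"]), 3L)
  expect_equal(unname(ms$routes["unrelated_co_thread"]), 2L)
  expect_equal(unname(ms$routes["lurking_presumed"]), 2L)
  expect_equal(ms$depth, 3L)
  expect_equal(ms$n_nodes, 68L)
  expect_equal(unname(ms$self_promotion["A"]), 51L)
})

test_that("tie-break policy is selectable and changes only the source choice", {
  # B co-participates in two of A's metaphor threads before first use; a
  # second earlier adopter gives latest/earliest different qualifying posts
  f <- quick_forum(
    list("O", c("O", "P"), "P", c("P", "Q"), c("O", "Q"), "Q"),
    texts = list("legacy of stroke begins",      # O first use (t1)
                 c("legacy of stroke again", "nice"),  # P exposed by O (t2)
                 "legacy of stroke from p",      # P first use (t3)
                 c("legacy of stroke by p", "hello"),  # Q exposed by P (t4)
                 c("legacy of stroke by o", "hi"),     # Q exposed by O (t5)
                 "legacy of stroke from q")      # Q first use (t6)
  )
  early <- infer_forum(f, tie_break = "earliest")$exposures
  late <- infer_forum(f, tie_break = "latest")$exposures
  expect_equal(early$source[early$adopter == "Q"], "P")
  expect_equal(late$source[late$adopter == "Q"], "O")
  expect_equal(early$route[early$adopter == "Q"],
               late$route[late$adopter == "Q"])
})
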
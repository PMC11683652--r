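# Synthetic forum generator with a planted diffusion process.
#
# The generator emulates the statistical structure the inference assumes:
# heavy-tailed per-user activity (Zipf weights), threads of shifted-Poisson
# size generated in chronological order, a single phrase originator, a
# per-thread self-promotion rate for adopters, certain exposure for posters
# of phrase-bearing threads, Bernoulli lurking exposure for non-posters, and
# a one-shot adoption coin at first exposure. Everything is driven by one
# seed, so identical configs yield byte-identical archives.

#' Synthetic forum configuration
#'
#' @param n_users number of users.
#' @param n_threads number of threads (generated in chronological order; a
#'   thread's posts are contiguous in the global ordinal).
#' @param mean_thread_size mean posts per thread (shifted Poisson, minimum 1).
#' @param activity_exponent Zipf exponent for per-user posting propensity
#'   (user r has weight r^-exponent); ~1 reproduces the superuser skew of
#'   real communities.
#' @param origin_thread thread ordinal of the first phrase use; the most
#'   active user is the originator and is forced into this thread.
#' @param self_promotion_rate probability an adopter includes the phrase
#'   (once) in a thread they post in after adopting.
#' @param adoption_prob probability a user adopts at their FIRST exposure;
#'   users failing this one coin never adopt (see the methods vignette).
#' @param lurk_prob probability a non-posting, not-yet-exposed user reads a
#'   given phrase-bearing thread.
#' @param seed integer RNG seed; fully determines the output.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_users = 200L, n_threads = 500L,
                             mean_thread_size = 3, activity_exponent = 1,
                             origin_thread = 2L, self_promotion_rate = 0.3,
                             adoption_prob = 0.2, lurk_prob = 0.1,
                             seed = 1L) {
  cfg <- list(n_users = as.integer(n_users), n_threads = as.integer(n_threads),
              mean_thread_size = as.numeric(mean_thread_size),
              activity_exponent = as.numeric(activity_exponent),
              origin_thread = as.integer(origin_thread),
              self_promotion_rate = as.numeric(self_promotion_rate),
              adoption_prob = as.numeric(adoption_prob),
              lurk_prob = as.numeric(lurk_prob), seed = as.integer(seed))
  if (cfg$n_users < 1L) stop_fmt("n_users must be >= 1")
  if (cfg$n_threads < 1L) stop_fmt("n_threads must be >= 1")
  if (cfg$mean_thread_size < 1) stop_fmt("mean_thread_size must be >= 1")
  if (cfg$origin_thread < 1L || cfg$origin_thread > cfg$n_threads) {
    stop_fmt("origin_thread must lie in 1..n_threads")
  }
  for (p in c("self_promotion_rate", "adoption_prob", "lurk_prob")) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 0 || cfg[[p]] > 1) {
      stop_fmt("%s must be a probability in [0, 1]", p)
    }
  }
  structure(cfg, class = "synthetic_config")
}

# filler vocabulary; deliberately free of the phrase keywords and synonyms
# so every planted phrase post is exactly one detector hit.
filler_words <- c("rest", "sleep", "today", "week", "walk", "hospital",
                  "doctor", "better", "hope", "slow", "morning", "tea",
                  "garden", "family", "visit", "good", "day", "feeling",
                  "thanks", "update", "progress", "appointment")

phrase_sentence <- function() {
  paste("after my stroke fatigue is a legacy of stroke",
        paste(sample(filler_words, 3, replace = TRUE), collapse = " "))
}

filler_sentence <- function() {
  paste(sample(filler_words, 6, replace = TRUE), collapse = " ")
}

#' Generate a synthetic forum with planted diffusion ground truth
#'
#' @param config a [synthetic_config()].
#' @return object of class `synthetic_forum`: list with
#'   \describe{
#'     \item{forum}{the emitted `ohc_forum` (chronological, contiguous threads).}
#'     \item{profiles}{profiles data.frame with synthetic demographics and tallied counts.}
#'     \item{truth}{`synthetic_truth`: originator, exposure log, adoption log
#'       (with `expressed` flags), planted adoption edges and planted depth.}
#'     \item{pattern}{the [stroke_legacy_pattern()] the planted phrase matches.}
#'     \item{config}{the input config.}
#'   }
#' @export
generate_forum <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  n_users <- config$n_users
  users <- sprintf("u%04d", seq_len(n_users))
  w <- seq_len(n_users)^(-config$activity_exponent)
  originator <- users[1]  # highest propensity: the superuser-originator trait

  adopted <- stats::setNames(rep(FALSE, n_users), users)
  adopt_thread <- stats::setNames(rep(NA_integer_, n_users), users)
  exposed <- stats::setNames(rep(FALSE, n_users), users)
  adopted[originator] <- TRUE
  adopt_thread[originator] <- config$origin_thread  # active from origin on

  posts_author <- character(); posts_thread <- character()
  posts_text <- character(); phrase_flag <- logical()
  exp_user <- character(); exp_thread <- character(); exp_via <- character()
  ad_user <- character(); ad_source <- character()
  ad_mech <- character(); ad_thread <- character()

  for (t in seq_len(config$n_threads)) {
    tid <- sprintf("t%05d", t)
    k <- 1L + stats::rpois(1, config$mean_thread_size - 1)
    authors <- sample(users, k, replace = TRUE, prob = w)
    if (t == config$origin_thread && !(originator %in% authors)) {
      authors <- c(authors, originator)
    }
    uniq <- unique(authors)

    # which participants write the phrase in this thread (once each, on
    # their first post here)
    phrase_users <- character()
    for (a in uniq) {
      if (a == originator && t == config$origin_thread) {
        phrase_users <- c(phrase_users, a)
      } else if (adopted[a] && !is.na(adopt_thread[a]) && adopt_thread[a] < t &&
                 stats::runif(1) < config$self_promotion_rate) {
        phrase_users <- c(phrase_users, a)
      }
    }

    used_phrase <- stats::setNames(rep(FALSE, length(uniq)), uniq)
    first_phrase_author <- NA_character_
    for (a in authors) {
      is_phrase <- a %in% phrase_users && !used_phrase[a]
      if (is_phrase) {
        used_phrase[a] <- TRUE
        if (is.na(first_phrase_author)) first_phrase_author <- a
        posts_text <- c(posts_text, phrase_sentence())
      } else {
        posts_text <- c(posts_text, filler_sentence())
      }
      posts_author <- c(posts_author, a)
      posts_thread <- c(posts_thread, tid)
      phrase_flag <- c(phrase_flag, is_phrase)
    }

    if (length(phrase_users)) {
      # posting exposure is certain for every participant
      for (u in uniq) {
        exp_user <- c(exp_user, u); exp_thread <- c(exp_thread, tid)
        exp_via <- c(exp_via, "posting")
        if (!exposed[u]) {
          exposed[u] <- TRUE
          if (!adopted[u] && stats::runif(1) < config$adoption_prob) {
            adopted[u] <- TRUE; adopt_thread[u] <- t
            ad_user <- c(ad_user, u); ad_source <- c(ad_source, first_phrase_author)
            ad_mech <- c(ad_mech, "posting"); ad_thread <- c(ad_thread, tid)
          }
        }
      }
      # lurking exposure for not-yet-exposed non-posters
      if (config$lurk_prob > 0) {
        cand <- users[!exposed & !(users %in% uniq)]
        if (length(cand)) {
          lurk <- cand[stats::runif(length(cand)) < config$lurk_prob]
          for (v in lurk) {
            exposed[v] <- TRUE
            exp_user <- c(exp_user, v); exp_thread <- c(exp_thread, tid)
            exp_via <- c(exp_via, "lurking")
            if (stats::runif(1) < config$adoption_prob) {
              adopted[v] <- TRUE; adopt_thread[v] <- t
              ad_user <- c(ad_user, v); ad_source <- c(ad_source, first_phrase_author)
              ad_mech <- c(ad_mech, "lurking"); ad_thread <- c(ad_thread, tid)
            }
          }
        }
      }
    }
  }

  posts <- data.frame(thread_id = posts_thread, author = posts_author,
                      text = posts_text, stringsAsFactors = FALSE)
  forum <- as_forum(posts)

  phrase_posts <- data.frame(
    post_index = forum$posts$post_index[phrase_flag],
    thread_id = posts_thread[phrase_flag],
    author = posts_author[phrase_flag],
    stringsAsFactors = FALSE
  )
  expressed_users <- unique(phrase_posts$author)

  adoptions <- data.frame(user = ad_user, source = ad_source,
                          mechanism = ad_mech, thread_id = ad_thread,
                          stringsAsFactors = FALSE)
  adoptions$expressed <- adoptions$user %in% expressed_users
  planted <- adoptions[adoptions$expressed, c("user", "source"), drop = FALSE]
  planted_edges <- data.frame(source = planted$source,
                              recipient = planted$user,
                              stringsAsFactors = FALSE)
  truth <- structure(list(
    originator = originator,
    users = users,
    exposures = data.frame(user = exp_user, thread_id = exp_thread,
                           via = exp_via, stringsAsFactors = FALSE),
    adoptions = adoptions,
    planted_edges = planted_edges,
    planted_depth = tree_depth(planted_edges, originator),
    phrase_posts = phrase_posts
  ), class = "synthetic_truth")

  profiles <- synth_profiles(forum, phrase_posts, users)

  structure(list(forum = forum, profiles = profiles, truth = truth,
                 pattern = stroke_legacy_pattern(), config = config),
            class = "synthetic_forum")
}

synth_profiles <- function(forum, phrase_posts, users) {
  counts <- table(forum$posts$author)
  total <- as.integer(ifelse(users %in% names(counts), counts[users], 0L))
  uses <- if (nrow(phrase_posts)) {
    tapply(phrase_posts$thread_id, phrase_posts$author,
           function(t) length(unique(t)))
  } else integer()
  n <- length(users)
  age_at <- pmin(90L, pmax(18L, as.integer(round(stats::rnorm(n, 55, 14)))))
  since <- sample(0:12, n, replace = TRUE)
  data.frame(
    user = users,
    age_when_posting = age_at + since,
    age_at_stroke = age_at,
    time_since_stroke = since,
    sex = sample(c("F", "M"), n, replace = TRUE),
    identity = sample(c("survivor", "caregiver"), n, replace = TRUE,
                      prob = c(0.8, 0.2)),
    times_metaphor_used = as.integer(ifelse(users %in% names(uses),
                                            uses[users], 0L)),
    total_posts = total,
    stringsAsFactors = FALSE
  )
}

#' @export
print.synthetic_forum <- function(x, ...) {
  cat(sprintf("<synthetic_forum> seed %d: %d posts, %d threads, %d users; %d phrase posts, %d planted adopters\n",
              x$config$seed, nrow(x$forum$posts), nrow(x$forum$threads),
              length(x$forum$users), nrow(x$truth$phrase_posts),
              nrow(x$truth$adoptions) + 1L))
  invisible(x)
}

#' Write a synthetic forum bundle to disk
#'
#' Emits the canonical posts CSV, profiles CSV, pattern JSON, and ground
#' truth JSON into a directory.
#'
#' @param sf a `synthetic_forum`.
#' @param dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_synthetic <- function(sf, dir) {
  stopifnot(inherits(sf, "synthetic_forum"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(posts = file.path(dir, "posts.csv"),
             profiles = file.path(dir, "profiles.csv"),
             pattern = file.path(dir, "pattern.json"),
             truth = file.path(dir, "ground_truth.json"))
  write_forum(sf$forum, paths[["posts"]])
  utils::write.csv(sf$profiles, paths[["profiles"]], row.names = FALSE,
                   fileEncoding = "UTF-8")
  write_pattern(sf$pattern, paths[["pattern"]])
  jsonlite::write_json(unclass(sf$truth), paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Score inferred diffusion against planted ground truth
#'
#' Compares inferred adoption edges with the planted edges of expressed
#' adopters (those with at least one phrase post; silent planted adopters are
#' unobservable in the archive by construction). An inferred edge matches
#' when adopter and source agree; presumed-lurking records carry no source
#' and never match. Also reports the route confusion matrix (planted
#' first-exposure channel vs inferred route) and the depth difference of the
#' adoption-edge trees.
#'
#' @param exposures inferred [classify_exposure()] records.
#' @param tree the inferred `diffusion_tree`.
#' @param truth a `synthetic_truth`.
#' @return list with `precision`, `recall`, `confusion` (table), `depth_diff`,
#'   `n_inferred`, `n_planted`, `degenerate`.
#' @export
recovery_metrics <- function(exposures, tree, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  inferred_users <- unique(c(exposures$adopter,
                             exposures$source[!is.na(exposures$source)],
                             if (!is.na(tree$root)) tree$root))
  stray <- setdiff(inferred_users, truth$users)
  if (length(stray)) {
    stop_fmt("inferred users absent from the synthetic universe: %s",
             paste(stray, collapse = ", "))
  }
  planted <- truth$adoptions[truth$adoptions$expressed, , drop = FALSE]
  n_inf <- nrow(exposures)
  n_pl <- nrow(planted)
  if (n_inf == 0L && n_pl == 0L) {
    return(list(precision = 1, recall = 1,
                confusion = table(character(), character()),
                depth_diff = 0L, n_inferred = 0L, n_planted = 0L,
                degenerate = TRUE))
  }
  inf_key <- paste(exposures$adopter, exposures$source, sep = "\r")
  inf_key[is.na(exposures$source)] <- NA_character_
  pl_key <- paste(planted$user, planted$source, sep = "\r")
  n_match <- sum(!is.na(inf_key) & inf_key %in% pl_key)
  precision <- if (n_inf) n_match / n_inf else 1
  recall <- if (n_pl) n_match / n_pl else 1

  common <- intersect(exposures$adopter, planted$user)
  confusion <- table(
    planted = planted$mechanism[match(common, planted$user)],
    inferred = exposures$route[match(common, exposures$adopter)]
  )
  ad_edges <- tree$edges[tree$edges$kind == "adoption", , drop = FALSE]
  inferred_depth <- if (is.na(tree$root)) 0L else tree_depth(ad_edges, tree$root)
  list(precision = precision, recall = recall, confusion = confusion,
       depth_diff = inferred_depth - truth$planted_depth,
       n_inferred = n_inf, n_planted = n_pl, degenerate = FALSE)
}

#' Run the full inference chain on a synthetic forum
#'
#' Convenience wrapper: detect mentions with the bundle's pattern, confirm by
#' context rule, detect adoptions, classify exposure, build the tree, and
#' score recovery against the planted truth.
#'
#' @param sf a `synthetic_forum`.
#' @param tie_break passed to [classify_exposure()].
#' @return list with `mentions`, `adoptions`, `exposures`, `tree`, `metrics`.
#' @export
infer_synthetic <- function(sf, tie_break = "earliest") {
  stopifnot(inherits(sf, "synthetic_forum"))
  mentions <- apply_context_rule(find_candidates(sf$forum, sf$pattern),
                                 sf$pattern, sf$forum)
  adoptions <- detect_adoptions(mentions)
  exposures <- classify_exposure(sf$forum, mentions, adoptions,
                                 tie_break = tie_break)
  tree <- build_diffusion_tree(sf$forum, mentions, exposures, adoptions)
  list(mentions = mentions, adoptions = adoptions, exposures = exposures,
       tree = tree, metrics = recovery_metrics(exposures, tree, sf$truth))
}
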
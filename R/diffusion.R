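# Diffusion inference: adoption timelines, exposure-route classification,
# diffusion-tree construction, mechanism labels, and depth.
#
# All temporal reasoning compares global post ordinals. Thread membership
# (>= 1 post), not post adjacency, is the exposure criterion: members of a
# thread are assumed to read it, including posts added after their own.

# per-(author, thread) earliest post ordinal; the workhorse lookup table.
user_thread_first <- function(forum) {
  posts <- forum$posts
  if (!nrow(posts)) {
    return(data.frame(author = character(), thread_id = character(),
                      first_index = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(posts$author, posts$thread_id, sep = "\r")
  first <- tapply(posts$post_index, key, min)
  parts <- strsplit(names(first), "\r", fixed = TRUE)
  data.frame(
    author = vapply(parts, `[`, character(1), 1L),
    thread_id = vapply(parts, `[`, character(1), 2L),
    first_index = as.integer(first),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Participation timeline of one user
#'
#' The ordered list of threads the user took part in (by the user's earliest
#' post in each; every thread once), with each thread flagged
#' `metaphor_by_user`, `metaphor_by_other`, or `no_metaphor`. This is the
#' per-participant engagement strip of the analysis: the threads where the
#' user wrote the phrase highlighted against their background activity.
#'
#' @param forum an `ohc_forum`.
#' @param user author id.
#' @param mentions mentions data.frame (confirmed rows are used).
#' @return data.frame `thread_id`, `thread_number`, `first_post_index`, `flag`.
#' @export
participation_timeline <- function(forum, user, mentions = NULL) {
  stopifnot(inherits(forum, "ohc_forum"))
  if (!user %in% forum$users) stop_fmt("unknown user: %s", user)
  rows <- forum$posts[forum$posts$author == user, , drop = FALSE]
  first <- tapply(rows$post_index, rows$thread_id, min)
  out <- data.frame(
    thread_id = names(first),
    first_post_index = as.integer(first),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$first_post_index), , drop = FALSE]
  out$thread_number <- thread_number(forum, out$thread_id)
  flag <- rep("no_metaphor", nrow(out))
  if (!is.null(mentions)) {
    conf <- confirmed_mentions(mentions)
    by_other <- unique(conf$thread_id[conf$author != user])
    by_user <- unique(conf$thread_id[conf$author == user])
    flag[out$thread_id %in% by_other] <- "metaphor_by_other"
    flag[out$thread_id %in% by_user] <- "metaphor_by_user"  # takes precedence
  }
  out$flag <- flag
  rownames(out) <- NULL
  out[, c("thread_id", "thread_number", "first_post_index", "flag")]
}

#' Detect adoption events from the mention set
#'
#' One event per distinct confirmed-mention author, ordered by first use; the
#' earliest event is the root adopter (the phrase originator, under the
#' single-origination assumption). Each event carries the user's distinct
#' metaphor threads, ordered by the user's first metaphor post in each —
#' "each thread only once" however many metaphor posts it holds.
#'
#' @param mentions mentions data.frame.
#' @return data.frame `user`, `first_use_post_index`, `first_use_thread`,
#'   `n_metaphor_threads`, plus a list column `metaphor_threads`; zero rows
#'   for an empty mention set.
#' @export
detect_adoptions <- function(mentions) {
  conf <- confirmed_mentions(mentions)
  if (!nrow(conf)) {
    return(data.frame(user = character(), first_use_post_index = integer(),
                      first_use_thread = character(),
                      n_metaphor_threads = integer(),
                      stringsAsFactors = FALSE))
  }
  conf <- conf[order(conf$post_index), , drop = FALSE]
  users <- unique(conf$author)
  ev <- lapply(users, function(u) {
    m <- conf[conf$author == u, , drop = FALSE]
    threads <- unique(m$thread_id)  # already in first-use order
    list(user = u,
         first_use_post_index = m$post_index[1],
         first_use_thread = m$thread_id[1],
         threads = threads)
  })
  out <- data.frame(
    user = vapply(ev, `[[`, character(1), "user"),
    first_use_post_index = vapply(ev, `[[`, integer(1), "first_use_post_index"),
    first_use_thread = vapply(ev, `[[`, character(1), "first_use_thread"),
    n_metaphor_threads = vapply(ev, function(e) length(e$threads), integer(1)),
    stringsAsFactors = FALSE
  )
  out$metaphor_threads <- I(lapply(ev, `[[`, "threads"))
  out <- out[order(out$first_use_post_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Self-promotion thread count
#'
#' Number of distinct threads in which a user posted the phrase — the
#' per-thread "times metaphor is used" count. For the originator this is the
#' self-promotion tally; for a single-use adopter it is 1.
#'
#' @param adoptions output of [detect_adoptions()].
#' @param user author id(s); defaults to every adopter.
#' @return named integer vector, user -> distinct metaphor threads.
#' @export
self_promotion_count <- function(adoptions, user = adoptions$user) {
  idx <- match(user, adoptions$user)
  if (anyNA(idx)) {
    stop_fmt("no adoption event for user(s): %s",
             paste(user[is.na(idx)], collapse = ", "))
  }
  stats::setNames(adoptions$n_metaphor_threads[idx], user)
}

#' Classify each non-root adopter's exposure route
#'
#' For adopter `u` with first phrase use at ordinal `p`, in order of
#' precedence:
#' \enumerate{
#'   \item `direct_metaphor_thread`: some thread `T` holds a phrase post by an
#'     earlier adopter at ordinal `< p`, and `u` posted in `T` (before or
#'     after that phrase post: membership implies reading). Source is the
#'     author of the earliest such qualifying phrase post (`tie_break =
#'     "latest"` selects the latest instead, for sensitivity analysis).
#'   \item `unrelated_co_thread`: `u` shares at least one thread of any topic
#'     with an earlier adopter, both users' posts there preceding `p`. Source
#'     is the co-participant whose co-presence was established earliest (the
#'     later of the two first posts in the shared thread is the moment
#'     co-presence exists).
#'   \item `lurking_presumed`: no shared thread with any earlier adopter —
#'     the phrase must have been read without posting; no source is named.
#' }
#'
#' @param forum an `ohc_forum`.
#' @param mentions mentions data.frame.
#' @param adoptions output of [detect_adoptions()] on the same mentions.
#' @param tie_break `"earliest"` (default) or `"latest"` qualifying exposure.
#' @return data.frame `adopter`, `route`, `source` (NA for lurking),
#'   `evidence_thread` (NA for lurking), `exposure_index` (ordinal of the
#'   qualifying exposure moment; NA for lurking).
#' @export
classify_exposure <- function(forum, mentions, adoptions,
                              tie_break = c("earliest", "latest")) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(forum, "ohc_forum"))
  if (!nrow(adoptions)) {
    return(data.frame(adopter = character(), route = character(),
                      source = character(), evidence_thread = character(),
                      exposure_index = integer(), stringsAsFactors = FALSE))
  }
  missing_users <- setdiff(adoptions$user, forum$users)
  if (length(missing_users)) {
    stop_fmt("adopter(s) absent from forum: %s",
             paste(missing_users, collapse = ", "))
  }
  conf <- confirmed_mentions(mentions)
  ut <- user_thread_first(forum)
  pick <- if (tie_break == "earliest") which.min else which.max

  out <- vector("list", nrow(adoptions) - 1L)
  for (i in seq_len(nrow(adoptions))[-1]) {
    u <- adoptions$user[i]
    p <- adoptions$first_use_post_index[i]
    u_threads <- ut[ut$author == u, , drop = FALSE]

    # (1) direct: earlier phrase post in a thread u belongs to
    qual <- conf[conf$post_index < p & conf$author != u &
                   conf$thread_id %in% u_threads$thread_id, , drop = FALSE]
    if (nrow(qual)) {
      j <- pick(qual$post_index)
      out[[i - 1L]] <- data.frame(
        adopter = u, route = "direct_metaphor_thread",
        source = qual$author[j], evidence_thread = qual$thread_id[j],
        exposure_index = qual$post_index[j], stringsAsFactors = FALSE)
      next
    }

    # (2) unrelated co-thread: shared thread with an earlier adopter,
    #     both first posts before p
    earlier <- adoptions$user[adoptions$first_use_post_index < p]
    earlier <- setdiff(earlier, u)
    cand <- NULL
    if (length(earlier)) {
      v_rows <- ut[ut$author %in% earlier & ut$first_index < p, , drop = FALSE]
      u_rows <- u_threads[u_threads$first_index < p, , drop = FALSE]
      shared <- merge(u_rows, v_rows, by = "thread_id",
                      suffixes = c("_u", "_v"))
      if (nrow(shared)) {
        shared$moment <- pmax(shared$first_index_u, shared$first_index_v)
        j <- pick(shared$moment)
        cand <- data.frame(
          adopter = u, route = "unrelated_co_thread",
          source = shared$author_v[j], evidence_thread = shared$thread_id[j],
          exposure_index = shared$moment[j], stringsAsFactors = FALSE)
      }
    }
    if (!is.null(cand)) {
      out[[i - 1L]] <- cand
      next
    }

    # (3) lurking: no observable contact with any earlier adopter
    out[[i - 1L]] <- data.frame(
      adopter = u, route = "lurking_presumed",
      source = NA_character_, evidence_thread = NA_character_,
      exposure_index = NA_integer_, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(adopter = character(), route = character(),
                      source = character(), evidence_thread = character(),
                      exposure_index = integer(), stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

route_mechanism <- c(direct_metaphor_thread = "self_promotion_exposure",
                     unrelated_co_thread = "social",
                     lurking_presumed = "lurking_presumed")

#' Build the diffusion tree
#'
#' Nodes are all adopters plus every distinct non-adopter co-participant of a
#' phrase-bearing thread (the recipients — users demonstrably exposed even if
#' they never adopt). Edges:
#' \itemize{
#'   \item one `adoption` edge into each non-root adopter, from the source of
#'     its exposure record; presumed lurkers attach to the root (who authored
#'     the bulk of the exposure opportunities), flagged `lurking_presumed`;
#'   \item one `spreading_instance` edge per (phrase poster, recipient) pair
#'     over the poster's metaphor threads.
#' }
#' Depth is the length in edges of the longest root-to-leaf path over all
#' edges; breadth (distinct recipients) is reported separately.
#'
#' @param forum an `ohc_forum`.
#' @param mentions mentions data.frame.
#' @param exposures output of [classify_exposure()].
#' @param adoptions optional [detect_adoptions()] result (recomputed if NULL).
#' @return object of class `diffusion_tree`: list with `root`, `nodes`
#'   (data.frame `id`, `role`, `is_root`), `edges` (data.frame `source`,
#'   `recipient`, `kind`, `mechanism`, `thread_id`), `depth`.
#' @export
build_diffusion_tree <- function(forum, mentions, exposures,
                                 adoptions = NULL) {
  if (is.null(adoptions)) adoptions <- detect_adoptions(mentions)
  conf <- confirmed_mentions(mentions)
  if (!nrow(adoptions)) {
    tree <- structure(list(
      root = NA_character_,
      nodes = data.frame(id = character(), role = character(),
                         is_root = logical(), stringsAsFactors = FALSE),
      edges = empty_edges(), depth = 0L), class = "diffusion_tree")
    return(tree)
  }
  root <- adoptions$user[1]
  adopters <- adoptions$user

  # adoption edges
  ad_edges <- empty_edges()
  if (nrow(exposures)) {
    src <- ifelse(is.na(exposures$source), root, exposures$source)
    ad_edges <- data.frame(
      source = src, recipient = exposures$adopter, kind = "adoption",
      mechanism = unname(route_mechanism[exposures$route]),
      thread_id = exposures$evidence_thread, stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ad_edges$recipient)) {
    stop_fmt("internal consistency error: adopter with multiple adoption edges")
  }

  # spreading edges: phrase poster -> non-adopter co-participant
  sp <- NULL
  if (nrow(conf)) {
    m_threads <- unique(conf[, c("author", "thread_id")])
    rows <- lapply(seq_len(nrow(m_threads)), function(j) {
      parts <- thread_participants(forum, m_threads$thread_id[j])
      rec <- setdiff(parts, adopters)
      if (!length(rec)) return(NULL)
      data.frame(source = m_threads$author[j], recipient = rec,
                 kind = "spreading_instance",
                 mechanism = "self_promotion_exposure",
                 thread_id = m_threads$thread_id[j], stringsAsFactors = FALSE)
    })
    sp <- do.call(rbind, rows)
    if (!is.null(sp)) {
      sp <- sp[!duplicated(sp[, c("source", "recipient")]), , drop = FALSE]
    }
  }
  edges <- rbind(ad_edges, sp %||% empty_edges())
  rownames(edges) <- NULL

  recipients <- setdiff(unique(edges$recipient[edges$kind == "spreading_instance"]),
                        adopters)
  nodes <- data.frame(
    id = c(adopters, recipients),
    role = c(rep("adopter", length(adopters)),
             rep("recipient", length(recipients))),
    is_root = c(adopters == root, rep(FALSE, length(recipients))),
    stringsAsFactors = FALSE
  )

  # cycle guard: adoption edges must respect first-use ordering
  fu <- stats::setNames(adoptions$first_use_post_index, adoptions$user)
  bad <- ad_edges$source %in% adoptions$user &
    fu[ad_edges$source] >= fu[ad_edges$recipient]
  if (nrow(ad_edges) && any(bad & ad_edges$mechanism != "lurking_presumed")) {
    stop_fmt("internal consistency error: adoption edge violates first-use order")
  }

  structure(list(root = root, nodes = nodes, edges = edges,
                 depth = tree_depth(edges, root)),
            class = "diffusion_tree")
}

empty_edges <- function() {
  data.frame(source = character(), recipient = character(),
             kind = character(), mechanism = character(),
             thread_id = character(), stringsAsFactors = FALSE)
}

#' Longest root-to-leaf path length
#'
#' Memoized depth-first longest path over the (acyclic) diffusion edge list:
#' adoption edges chain adopters; spreading edges terminate in recipients.
#'
#' @param edges data.frame with `source` and `recipient` columns.
#' @param root root node id.
#' @return non-negative integer depth (0 for a childless root).
#' @export
tree_depth <- function(edges, root) {
  if (!nrow(edges)) return(0L)
  kids <- split(edges$recipient, edges$source)
  memo <- new.env(parent = emptyenv())
  active <- new.env(parent = emptyenv())
  dfs <- function(v) {
    if (!is.null(memo[[v]])) return(memo[[v]])
    if (!is.null(active[[v]])) stop_fmt("cycle detected at node %s", v)
    active[[v]] <- TRUE
    ch <- unique(kids[[v]])
    d <- if (is.null(ch)) 0L else 1L + max(vapply(ch, dfs, integer(1)))
    rm(list = v, envir = active)
    memo[[v]] <- d
    d
  }
  dfs(as.character(root))
}

#' @export
print.diffusion_tree <- function(x, ...) {
  cat(sprintf("<diffusion_tree> root=%s; %d nodes (%d adopters, %d recipients); %d edges; depth %d\n",
              x$root, nrow(x$nodes), sum(x$nodes$role == "adopter"),
              sum(x$nodes$role == "recipient"), nrow(x$edges), x$depth))
  invisible(x)
}

#' Summarize diffusion mechanisms
#'
#' Per-user self-promotion thread counts, adopter counts by exposure route,
#' tree depth, node/recipient counts, and (when profiles are supplied) how
#' many non-root adopters are superusers.
#'
#' @param tree a `diffusion_tree`.
#' @param adoptions [detect_adoptions()] result.
#' @param profiles optional profiles data.frame with `user` and `total_posts`.
#' @param rule a [superuser_rule()] for the overlap count.
#' @return list of summary statistics.
#' @export
mechanism_summary <- function(tree, adoptions, profiles = NULL,
                              rule = superuser_rule()) {
  ad <- tree$edges[tree$edges$kind == "adoption", , drop = FALSE]
  mech_to_route <- stats::setNames(names(route_mechanism), route_mechanism)
  routes <- table(factor(unname(mech_to_route[ad$mechanism]),
                         levels = names(route_mechanism)))
  out <- list(
    n_nodes = nrow(tree$nodes),
    n_adopters = sum(tree$nodes$role == "adopter"),
    n_nonroot_adopters = max(0L, sum(tree$nodes$role == "adopter") - 1L),
    n_recipients = sum(tree$nodes$role == "recipient"),
    depth = tree$depth,
    routes = stats::setNames(as.integer(routes), names(routes)),
    self_promotion = if (nrow(adoptions)) self_promotion_count(adoptions)
                     else stats::setNames(integer(), character())
  )
  if (!is.null(profiles)) {
    su <- classify_superusers(
      stats::setNames(profiles$total_posts, profiles$user), rule)
    nonroot <- setdiff(adoptions$user, tree$root)
    out$superusers <- su
    out$n_superuser_nonroot_adopters <- length(intersect(nonroot, su))
  }
  out
}
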
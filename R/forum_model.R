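# Forum archive container: chronologically ordered posts in threads.
#
# The archive carries no timestamps; the 1-based global post ordinal
# (`post_index`) is the only temporal information, and every downstream
# "before/after" statement in the package is a comparison of these ordinals.

#' Construct a forum from a posts table
#'
#' Builds the validated forum container used by every analysis function. Posts
#' are sorted by their global chronological ordinal; threads are derived and
#' numbered 1-based by the ordinal of their earliest post (so "thread number 2"
#' means the thread whose first post is the second-earliest thread opener in
#' the archive). A thread's posts need not be contiguous in global order.
#'
#' @param posts data.frame with columns `thread_id`, `author`, `text`, and
#'   optionally `post_index` (1-based unique integers; defaults to row order)
#'   and `post_id` (opaque label, defaults to `post_index`).
#' @return An object of class `ohc_forum`: a list with
#'   \describe{
#'     \item{posts}{data.frame `post_index`, `post_id`, `thread_id`, `author`, `text`, sorted by `post_index`.}
#'     \item{threads}{data.frame `thread_id`, `thread_number`, `first_post_index`, `n_posts`.}
#'     \item{users}{character vector of distinct author ids (case-sensitive, as supplied).}
#'   }
#' @examples
#' f <- as_forum(data.frame(
#'   thread_id = c("t1", "t1", "t2"),
#'   author    = c("ann", "bob", "ann"),
#'   text      = c("hello", "hi", "new topic")
#' ))
#' f$threads
#' @export
as_forum <- function(posts) {
  stopifnot(is.data.frame(posts))
  need <- c("thread_id", "author", "text")
  missing_cols <- setdiff(need, names(posts))
  if (length(missing_cols)) {
    stop_fmt("posts table is missing required column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  n <- nrow(posts)
  if (is.null(posts$post_index)) {
    posts$post_index <- seq_len(n)
  }
  posts$post_index <- as.integer(posts$post_index)
  if (anyNA(posts$post_index) || (n && any(posts$post_index < 1L))) {
    stop_fmt("post_index must be positive integers")
  }
  dup <- unique(posts$post_index[duplicated(posts$post_index)])
  if (length(dup)) {
    stop_fmt("duplicate post_index value(s): %s",
             paste(sort(dup), collapse = ", "))
  }
  if (is.null(posts$post_id)) posts$post_id <- as.character(posts$post_index)
  posts$post_id   <- as.character(posts$post_id)
  posts$thread_id <- as.character(posts$thread_id)
  posts$author    <- as.character(posts$author)
  posts$text      <- as.character(posts$text)
  posts <- posts[order(posts$post_index),
                 c("post_index", "post_id", "thread_id", "author", "text"),
                 drop = FALSE]
  rownames(posts) <- NULL

  threads <- derive_threads(posts)
  structure(
    list(posts = posts, threads = threads, users = unique(posts$author)),
    class = "ohc_forum"
  )
}

# threads ranked by earliest post ordinal; idempotent by construction.
derive_threads <- function(posts) {
  if (!nrow(posts)) {
    return(data.frame(thread_id = character(), thread_number = integer(),
                      first_post_index = integer(), n_posts = integer(),
                      stringsAsFactors = FALSE))
  }
  first <- tapply(posts$post_index, posts$thread_id, min)
  sizes <- tapply(posts$post_index, posts$thread_id, length)
  ord <- order(first)
  data.frame(
    thread_id = names(first)[ord],
    thread_number = seq_along(first),
    first_post_index = as.integer(first[ord]),
    n_posts = as.integer(sizes[ord]),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' @export
print.ohc_forum <- function(x, ...) {
  cat(sprintf("<ohc_forum> %d posts, %d threads, %d users\n",
              nrow(x$posts), nrow(x$threads), length(x$users)))
  invisible(x)
}

#' Read a forum archive from disk
#'
#' Accepts CSV (UTF-8, header `post_id,thread_id,author,text`, optionally
#' `post_index`) or JSON-lines with the same keys. When no explicit ordinal
#' column is present, row order is taken as chronological order.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"jsonl"`; default guesses from the extension.
#' @return an [as_forum()] object.
#' @export
read_forum <- function(path, dialect = c("auto", "csv", "jsonl")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_fmt("forum file not found: %s", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "csv"
  }
  df <- if (dialect == "csv") {
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8")
  } else {
    lines <- readLines(path, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      data.frame(thread_id = character(), author = character(),
                 text = character(), stringsAsFactors = FALSE)
    } else {
      recs <- lapply(lines, jsonlite::fromJSON)
      do.call(rbind, lapply(recs, function(r) {
        as.data.frame(r[lengths(r) == 1L], stringsAsFactors = FALSE)
      }))
    }
  }
  need <- c("thread_id", "author", "text")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_fmt("%s is missing required column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  if (!is.null(df$post_index)) df$post_index <- as.integer(df$post_index)
  as_forum(df)
}

#' Write a forum in canonical CSV form
#'
#' The canonical dialect always carries an explicit `post_index` column, so a
#' write/read cycle is the identity on the container.
#'
#' @param forum an `ohc_forum`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_forum <- function(forum, path) {
  stopifnot(inherits(forum, "ohc_forum"))
  utils::write.csv(forum$posts, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Participants of a thread
#'
#' The set of authors with at least one post in the thread. Each user counts
#' once however many posts they contributed: thread membership, not posting
#' volume, is the unit of all co-participation reasoning.
#'
#' @param forum an `ohc_forum`.
#' @param thread_id thread identifier.
#' @return character vector of author ids, ordered by each author's first post
#'   in the thread.
#' @export
thread_participants <- function(forum, thread_id) {
  stopifnot(inherits(forum, "ohc_forum"))
  rows <- forum$posts[forum$posts$thread_id == thread_id, , drop = FALSE]
  if (!nrow(rows)) stop_fmt("unknown thread: %s", thread_id)
  unique(rows$author)
}

#' Structural validation report for a forum
#'
#' Pure report, never mutates or raises: duplicate ordinals (impossible after
#' [as_forum()] but checked for externally built tables), empty texts, the
#' fraction of single-author threads, and per-user post counts.
#'
#' @param forum an `ohc_forum`.
#' @return list with elements `issues` (character), `duplicate_post_index`,
#'   `empty_text_post_index`, `single_author_thread_fraction`, `post_counts`.
#' @export
validate_forum <- function(forum) {
  stopifnot(inherits(forum, "ohc_forum"))
  posts <- forum$posts
  issues <- character()

  dup <- unique(posts$post_index[duplicated(posts$post_index)])
  if (length(dup)) {
    issues <- c(issues, sprintf("duplicate post_index: %s",
                                paste(sort(dup), collapse = ", ")))
  }
  empty <- posts$post_index[!nzchar(trimws(posts$text))]
  if (length(empty)) {
    issues <- c(issues, sprintf("%d post(s) with empty text", length(empty)))
  }
  single_frac <- if (nrow(forum$threads)) {
    authors_per_thread <- tapply(posts$author, posts$thread_id,
                                 function(a) length(unique(a)))
    mean(authors_per_thread == 1L)
  } else NA_real_
  counts <- table(posts$author)
  list(
    issues = issues,
    duplicate_post_index = as.integer(sort(dup)),
    empty_text_post_index = as.integer(empty),
    single_author_thread_fraction = unname(single_frac),
    post_counts = sort_by_name(stats::setNames(as.integer(counts), names(counts)))
  )
}

#' Map thread ids to thread numbers
#'
#' @param forum an `ohc_forum`.
#' @param thread_id character vector of thread ids.
#' @return integer vector of 1-based thread numbers (rank by earliest post).
#' @export
thread_number <- function(forum, thread_id) {
  idx <- match(thread_id, forum$threads$thread_id)
  if (anyNA(idx)) {
    stop_fmt("unknown thread(s): %s",
             paste(thread_id[is.na(idx)], collapse = ", "))
  }
  forum$threads$thread_number[idx]
}
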
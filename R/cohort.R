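# Participant cohort: profiles, superuser classification, demographic summary.

#' Superuser classification rule
#'
#' Two definitions of "superuser" circulate for online health communities and
#' both are supported: the top percentage of users ranked by total posts
#' (`mode = "top_percent"`, default 1%), and a strict minimum-posts cutoff
#' (`mode = "min_posts"`, default > 100 posts). The min-posts form is the
#' package default because it is the one that can be checked row-by-row
#' against a published participant table.
#'
#' @param mode `"min_posts"` or `"top_percent"`.
#' @param min_posts strict threshold: superuser iff total posts `> min_posts`.
#' @param top_percent percentage of the user base (ceiling; ties at the cutoff
#'   count are all included).
#' @return an object of class `superuser_rule`.
#' @export
superuser_rule <- function(mode = c("min_posts", "top_percent"),
                           min_posts = 100L, top_percent = 1.0) {
  mode <- match.arg(mode)
  structure(list(mode = mode, min_posts = as.numeric(min_posts),
                 top_percent = as.numeric(top_percent)),
            class = "superuser_rule")
}

#' Classify superusers from per-user post counts
#'
#' @param post_counts named numeric vector, user id -> total posts.
#' @param rule a [superuser_rule()].
#' @return character vector of superuser ids (possibly empty).
#' @examples
#' counts <- c(A = 4932, B = 542, C = 178, D = 19, E = 2, F = 291, G = 58, H = 27)
#' classify_superusers(counts, superuser_rule("min_posts", 100)) # A B C F
#' @export
classify_superusers <- function(post_counts, rule = superuser_rule()) {
  stopifnot(inherits(rule, "superuser_rule"))
  if (!length(post_counts)) return(character())
  if (any(post_counts < 0)) stop_fmt("post counts must be non-negative")
  if (rule$mode == "min_posts") {
    sort(names(post_counts)[post_counts > rule$min_posts])
  } else {
    k <- ceiling(rule$top_percent / 100 * length(post_counts))
    if (k <= 0L) return(character())
    cutoff <- sort(post_counts, decreasing = TRUE)[k]
    sort(names(post_counts)[post_counts >= cutoff])
  }
}

#' Read participant profiles
#'
#' CSV with columns `user, age_when_posting, age_at_stroke, time_since_stroke,
#' sex, identity, times_metaphor_used, total_posts` (and optionally
#' `superuser` as yes/no, recomputed on demand from `total_posts`).
#'
#' @param path CSV path.
#' @return data.frame of profiles.
#' @export
read_profiles <- function(path) {
  if (!file.exists(path)) stop_fmt("profiles file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("user", "total_posts")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_fmt("%s is missing required column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  for (col in c("age_when_posting", "age_at_stroke", "time_since_stroke",
                "times_metaphor_used", "total_posts")) {
    if (!is.null(df[[col]])) df[[col]] <- as.numeric(df[[col]])
  }
  if (!is.null(df$superuser)) {
    df$superuser <- tolower(as.character(df$superuser)) %in% c("yes", "true", "1")
  }
  df
}

#' The packaged participant table
#'
#' The eight-row characteristics table of the metaphor-using cohort (ages,
#' time since stroke, sex, survivor/caregiver identity, per-user metaphor use
#' and total posts) that the package's fixture analyses are checked against.
#'
#' @return data.frame of 8 profiles.
#' @export
table1_profiles <- function() {
  read_profiles(system.file("extdata", "table1_participants.csv",
                            package = "ohcdiffusion", mustWork = TRUE))
}

#' Summarize a participant cohort
#'
#' Arithmetic means of age-when-posting and age-at-stroke (rounded half-up to
#' integer years), identity and sex counts, total metaphor uses, and superuser
#' count under the given rule. Because published cohort descriptions are
#' sometimes ambiguous about whether caregiver rows enter the age means, both
#' the all-rows means (the default headline values) and survivor-only means
#' are reported side by side. Rows missing a numeric field are excluded from
#' that mean and counted in `n_missing`.
#'
#' @param profiles data.frame as from [read_profiles()].
#' @param rule a [superuser_rule()] applied to `total_posts`.
#' @return list of summary statistics.
#' @export
summarize_cohort <- function(profiles, rule = superuser_rule()) {
  stopifnot(nrow(profiles) >= 1L)
  mean_int <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_integer_)
    as.integer(round_half_up(mean(x)))
  }
  surv <- profiles[profiles$identity == "survivor", , drop = FALSE]
  su <- classify_superusers(
    stats::setNames(profiles$total_posts, profiles$user), rule)
  list(
    n = nrow(profiles),
    mean_age_when_posting = mean_int(profiles$age_when_posting),
    mean_age_at_stroke = mean_int(profiles$age_at_stroke),
    mean_age_when_posting_survivors = mean_int(surv$age_when_posting),
    mean_age_at_stroke_survivors = mean_int(surv$age_at_stroke),
    n_missing = sum(is.na(profiles$age_when_posting) |
                      is.na(profiles$age_at_stroke)),
    identity_counts = sort_by_name(table_to_int(profiles$identity)),
    sex_counts = sort_by_name(table_to_int(profiles$sex)),
    total_metaphor_uses = sum(profiles$times_metaphor_used, na.rm = TRUE),
    superusers = su,
    n_superusers = length(su)
  )
}

table_to_int <- function(x) {
  tab <- table(x)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build profiles from a forum and a mention set
#'
#' Derives the countable profile columns (total posts, per-user metaphor
#' thread counts, superuser flag) directly from the archive, for forums whose
#' demographic table is absent (e.g. synthetic ones).
#'
#' @param forum an `ohc_forum`.
#' @param mentions a mentions data.frame (confirmed rows are counted).
#' @param rule a [superuser_rule()].
#' @return data.frame `user, times_metaphor_used, total_posts, superuser`.
#' @export
profiles_from_forum <- function(forum, mentions, rule = superuser_rule()) {
  counts <- table(forum$posts$author)
  conf <- confirmed_mentions(mentions)
  uses <- if (nrow(conf)) {
    tapply(conf$thread_id, conf$author, function(t) length(unique(t)))
  } else integer()
  users <- sort(names(counts))
  total <- as.integer(counts[users])
  su <- classify_superusers(stats::setNames(as.numeric(total), users), rule)
  data.frame(
    user = users,
    times_metaphor_used = as.integer(ifelse(users %in% names(uses),
                                            uses[users], 0L)),
    total_posts = total,
    superuser = users %in% su,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
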
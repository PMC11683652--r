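# Phrase mention detection: keyword/variant search, an automatable context
# rule, manual annotation merge, and a local-corpus frequency counter used as
# the desk-scale novelty check.

#' Define a phrase pattern
#'
#' A pattern bundles the word forms searched for (keywords such as "legacy"
#' and "legacies", plus synonym/misspelling variants such as "heritage" and
#' "footprint") with the context terms used by the automatic confirmation
#' rule. Matching is case-insensitive at word boundaries; variants may be
#' multi-word and are then matched as token sequences.
#'
#' @param canonical the canonical phrase, e.g. `"legacy of stroke"`.
#' @param keywords non-empty character vector of primary word forms.
#' @param synonyms character vector of synonym/misspelling variants.
#' @param context_terms character vector; a candidate is auto-confirmed when
#'   one of these occurs within `context_window` of the matched variant.
#' @param context_window `"same-post"` (default) or a non-negative integer
#'   token distance.
#' @return an object of class `phrase_pattern`.
#' @export
phrase_pattern <- function(canonical, keywords, synonyms = character(),
                           context_terms = character(),
                           context_window = "same-post") {
  keywords <- tolower(as.character(keywords))
  if (!length(keywords)) stop_fmt("keywords must be non-empty")
  if (!identical(context_window, "same-post")) {
    context_window <- as.integer(context_window)
    if (is.na(context_window) || context_window < 0L) {
      stop_fmt("context_window must be \"same-post\" or a non-negative integer")
    }
  }
  structure(
    list(canonical = as.character(canonical)[1],
         keywords = keywords,
         synonyms = tolower(as.character(synonyms)),
         context_terms = tolower(as.character(context_terms)),
         context_window = context_window),
    class = "phrase_pattern"
  )
}

#' @export
print.phrase_pattern <- function(x, ...) {
  cat(sprintf("<phrase_pattern> \"%s\"; %d keyword(s), %d synonym(s), %d context term(s)\n",
              x$canonical, length(x$keywords), length(x$synonyms),
              length(x$context_terms)))
  invisible(x)
}

#' The default stroke-legacy pattern
#'
#' The shipped pattern contains exactly the word forms named in the source
#' material for the "legacy of stroke" metaphor: keywords "legacy"/"legacies"
#' and the synonym variants "heritage" and "footprint", with post-stroke
#' context terms. No speculative misspellings are added: mention sets must be
#' reproducible from the config alone.
#'
#' @return a [phrase_pattern()].
#' @export
stroke_legacy_pattern <- function() {
  phrase_pattern(
    canonical = "legacy of stroke",
    keywords = c("legacy", "legacies"),
    synonyms = c("heritage", "footprint"),
    context_terms = c("stroke", "fatigue", "tired", "tiredness"),
    context_window = "same-post"
  )
}

#' Read a phrase pattern from a JSON config
#'
#' Keys: `canonical`, `keywords`, `synonyms`, `context_terms`,
#' `context_window`.
#'
#' @param path JSON file path.
#' @return a [phrase_pattern()].
#' @export
read_pattern <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  phrase_pattern(
    canonical = cfg$canonical,
    keywords = cfg$keywords,
    synonyms = cfg$synonyms %||% character(),
    context_terms = cfg$context_terms %||% character(),
    context_window = cfg$context_window %||% "same-post"
  )
}

#' Write a phrase pattern to a JSON config
#' @param pattern a [phrase_pattern()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pattern, path) {
  stopifnot(inherits(pattern, "phrase_pattern"))
  jsonlite::write_json(unclass(pattern), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# positions (first-token index) at which the variant's token sequence occurs
variant_positions <- function(tokens, variant_tokens) {
  k <- length(variant_tokens)
  n <- length(tokens)
  if (k == 0L || n < k) return(integer())
  if (k == 1L) return(which(tokens == variant_tokens))
  hits <- integer()
  for (i in seq_len(n - k + 1L)) {
    if (all(tokens[i:(i + k - 1L)] == variant_tokens)) hits <- c(hits, i)
  }
  hits
}

#' Find candidate phrase mentions
#'
#' Scans every post for the pattern's keyword and synonym variants. A post
#' containing a variant yields exactly one candidate per distinct variant hit
#' (a post repeating "legacy" twice is still one "legacy" candidate);
#' candidates are sorted by post ordinal.
#'
#' @param forum an `ohc_forum`.
#' @param pattern a [phrase_pattern()].
#' @return data.frame of mentions: `post_index`, `thread_id`, `author`,
#'   `variant`, `status` (all `"candidate"`), `topic` (all `"unlabeled"`).
#' @export
find_candidates <- function(forum, pattern) {
  stopifnot(inherits(forum, "ohc_forum"), inherits(pattern, "phrase_pattern"))
  variants <- unique(c(pattern$keywords, pattern$synonyms))
  vt <- tokenize(variants)
  toks <- tokenize(forum$posts$text)
  rows <- vector("list", nrow(forum$posts))
  for (i in seq_along(toks)) {
    hit <- variants[vapply(vt, function(v) length(variant_positions(toks[[i]], v)) > 0L,
                           logical(1))]
    if (length(hit)) {
      rows[[i]] <- data.frame(
        post_index = forum$posts$post_index[i],
        thread_id = forum$posts$thread_id[i],
        author = forum$posts$author[i],
        variant = hit,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(post_index = integer(), thread_id = character(),
                      author = character(), variant = character(),
                      stringsAsFactors = FALSE)
  }
  out$status <- rep("candidate", nrow(out))
  out$topic <- rep("unlabeled", nrow(out))
  out <- out[order(out$post_index, out$variant), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the automatic context-confirmation rule
#'
#' A candidate is auto-confirmed iff a context term occurs within
#' `context_window` tokens of the matched variant (or anywhere in the post
#' when the window is `"same-post"`). Everything else stays a candidate,
#' awaiting manual annotation — the rule is a proxy for manual semantic
#' coding, never an override of it.
#'
#' @param candidates output of [find_candidates()].
#' @param pattern the [phrase_pattern()].
#' @param forum the `ohc_forum` the candidates came from (needed to re-read
#'   post text for windowed matching).
#' @return the mentions data.frame with `status` in `{"confirmed","candidate"}`.
#' @export
apply_context_rule <- function(candidates, pattern, forum) {
  stopifnot(inherits(pattern, "phrase_pattern"))
  if (!nrow(candidates)) return(candidates)
  if (!length(pattern$context_terms)) return(candidates)
  idx <- match(candidates$post_index, forum$posts$post_index)
  toks <- tokenize(forum$posts$text[idx])
  win <- pattern$context_window
  ok <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    t <- toks[[i]]
    ctx_pos <- which(t %in% pattern$context_terms)
    if (!length(ctx_pos)) next
    if (identical(win, "same-post")) {
      ok[i] <- TRUE
    } else {
      vpos <- variant_positions(t, tokenize(candidates$variant[i])[[1]])
      ok[i] <- any(vapply(vpos, function(p) any(abs(ctx_pos - p) <= win),
                          logical(1)))
    }
  }
  candidates$status[ok] <- "confirmed"
  candidates
}

#' Merge manual annotations into the mention set
#'
#' Annotation decisions are authoritative: `confirm` promotes a candidate (and
#' attaches its topic label), `reject` demotes even a rule-confirmed mention.
#' The result is the definitive mention set used by every downstream module.
#'
#' @param mentions output of [apply_context_rule()] (or [find_candidates()]).
#' @param annotations data.frame `post_index`, `decision` (`confirm`/`reject`),
#'   `topic` (`fatigue`/`other`, optional); or `NULL` for no annotations.
#' @return mentions with final `status` (`confirmed`/`candidate`/`rejected`)
#'   and `topic` labels.
#' @export
merge_annotations <- function(mentions, annotations = NULL) {
  if (is.null(annotations) || !nrow(annotations)) return(mentions)
  stopifnot(all(c("post_index", "decision") %in% names(annotations)))
  unknown <- setdiff(annotations$post_index, mentions$post_index)
  if (length(unknown)) {
    stop_fmt("annotation(s) reference post_index with no candidate mention: %s",
             paste(sort(unknown), collapse = ", "))
  }
  for (j in seq_len(nrow(annotations))) {
    sel <- mentions$post_index == annotations$post_index[j]
    if (identical(annotations$decision[j], "confirm")) {
      mentions$status[sel] <- "confirmed"
      if (!is.null(annotations$topic) && !is.na(annotations$topic[j]) &&
          nzchar(annotations$topic[j])) {
        mentions$topic[sel] <- annotations$topic[j]
      }
    } else if (identical(annotations$decision[j], "reject")) {
      mentions$status[sel] <- "rejected"
    } else {
      stop_fmt("unknown annotation decision: %s", annotations$decision[j])
    }
  }
  mentions
}

#' Confirmed mentions only
#' @param mentions a mentions data.frame.
#' @return the rows with `status == "confirmed"`.
#' @export
confirmed_mentions <- function(mentions) {
  out <- mentions[mentions$status == "confirmed", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Topic percentages over confirmed mentions
#'
#' Integer percentages, rounded half-up — 34 of 61 fatigue mentions print as
#' 56, the complementary 27 of 61 as 44.
#'
#' @param mentions a mentions data.frame.
#' @return named integer vector of percentages by topic.
#' @export
topic_percentages <- function(mentions) {
  conf <- confirmed_mentions(mentions)
  if (!nrow(conf)) return(stats::setNames(integer(), character()))
  tab <- table(conf$topic)
  pct <- round_half_up(100 * as.numeric(tab) / nrow(conf))
  sort_by_name(stats::setNames(as.integer(pct), names(tab)))
}

#' Count exact phrase strings in a local text corpus
#'
#' The desk-scale stand-in for web/reference-corpus novelty searches: exact,
#' case-insensitive, whitespace-normalized occurrence counts of each query
#' string over a set of plain-text files. All-zero counts set the novelty
#' flag for that corpus.
#'
#' @param corpus_files character vector of readable text file paths.
#' @param phrase_strings character vector of query strings.
#' @return list with `counts` (named integer vector per query string) and
#'   `novel` (TRUE iff every count is zero).
#' @export
corpus_frequency <- function(corpus_files, phrase_strings) {
  norm <- function(s) gsub("\\s+", " ", tolower(s))
  queries <- norm(phrase_strings)
  counts <- stats::setNames(integer(length(queries)), phrase_strings)
  for (f in corpus_files) {
    if (!file.exists(f)) stop_fmt("corpus file not readable: %s", f)
    text <- norm(paste(readLines(f, warn = FALSE, encoding = "UTF-8"),
                       collapse = " "))
    for (q in seq_along(queries)) {
      m <- gregexpr(queries[q], text, fixed = TRUE)[[1]]
      counts[q] <- counts[q] + if (m[1] == -1L) 0L else length(m)
    }
  }
  list(counts = counts, novel = all(counts == 0L))
}
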
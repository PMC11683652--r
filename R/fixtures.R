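# Packaged mini-forum fixture.
#
# A programmatically built archive consistent with the documented cascade
# narrative: the phrase first appears in thread 2; the originator A promotes
# it in 51 distinct threads; B, C and F are exposed directly in A's metaphor
# threads; D and H co-participate with A and B in unrelated threads; E and G
# never share a thread with any participant (presumed lurkers). Sixty distinct
# bystanders co-participate in metaphor threads, so the diffusion tree has
# 68 nodes and reaches depth 3 via A -> B -> H -> recipient.

#' The narrative mini-forum fixture
#'
#' @return list with `forum` (an `ohc_forum`), `annotations` (topic labels for
#'   the 61 phrase posts: 34 fatigue / 27 other, in chronological order),
#'   `pattern` (the [stroke_legacy_pattern()]), and `profiles`
#'   ([table1_profiles()]).
#' @export
narrative_forum <- function() {
  posts <- list()
  phrase_idx <- integer()
  n <- 0L
  add <- function(thread, author, phrase = FALSE, text = NULL) {
    n <<- n + 1L
    if (is.null(text)) {
      text <- if (phrase) {
        "the tiredness you describe is a legacy of stroke and it can last years"
      } else {
        "thank you all for the kind words and the update this week"
      }
    }
    posts[[n]] <<- data.frame(thread_id = thread, author = author,
                              text = text, stringsAsFactors = FALSE)
    if (phrase) phrase_idx <<- c(phrase_idx, n)
    invisible(NULL)
  }

  add("t001", "x02", text = "hello everyone hope the group is doing well")
  # thread 2: a relative asks for help with tiredness; A replies with the phrase
  add("t002", "x01", text = "my father had a stroke recently and is so tired all the time")
  add("t002", "A", phrase = TRUE,
      text = "fatigue is a stroke legacy he may tire easily in future a legacy of stroke")
  add("t002", "x01", text = "thank you that is reassuring to hear")
  # A's metaphor threads where B, C, F take part (their direct exposure)
  add("t003", "A", phrase = TRUE)
  add("t003", "B")
  add("t004", "A", phrase = TRUE)
  add("t004", "C")
  add("t005", "A", phrase = TRUE)
  add("t005", "F")
  # subsequent adopters' own metaphor threads
  add("t006", "B", phrase = TRUE); add("t006", "x03")
  add("t007", "C", phrase = TRUE); add("t007", "x04")
  add("t008", "F", phrase = TRUE); add("t008", "x05")
  add("t009", "F", phrase = TRUE); add("t009", "x06")
  add("t010", "F", phrase = TRUE); add("t010", "x07")
  add("t011", "B", phrase = TRUE); add("t011", "x08")
  # H co-participates with B in an unrelated thread, then adopts
  add("t012", "B"); add("t012", "H")
  add("t013", "H", phrase = TRUE); add("t013", "x09")
  # D co-participates with A in an unrelated thread, then adopts
  add("t014", "A"); add("t014", "D")
  add("t015", "D", phrase = TRUE); add("t015", "x10")
  # E and G never share a thread with any participant
  add("t016", "E", phrase = TRUE); add("t016", "x11"); add("t016", "x60")
  add("t017", "G", phrase = TRUE); add("t017", "x12"); add("t017", "x61")
  # A's remaining 47 self-promotion threads, one fresh bystander each
  for (i in seq_len(47)) {
    tid <- sprintf("t%03d", 17L + i)
    add(tid, "A", phrase = TRUE)
    add(tid, sprintf("x%02d", 12L + i))
  }

  forum <- as_forum(do.call(rbind, posts))
  topics <- rep(c("fatigue", "other"), c(34L, 27L))
  annotations <- data.frame(
    post_index = sort(phrase_idx),
    decision = "confirm",
    topic = topics,
    stringsAsFactors = FALSE
  )
  list(forum = forum, annotations = annotations,
       pattern = stroke_legacy_pattern(), profiles = table1_profiles())
}

#' Read a mention annotation table
#'
#' CSV with columns `post_index`, `decision` (`confirm`/`reject`) and optional
#' `topic`.
#'
#' @param path CSV path.
#' @return annotations data.frame.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_fmt("annotation file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("post_index", "decision")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_fmt("%s is missing required column(s): %s", path,
             paste(missing_cols, collapse = ", "))
  }
  df$post_index <- as.integer(df$post_index)
  df
}
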
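# Shared internal helpers.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed community statistics in this
#' domain (mean ages, topic percentages) conventionally round half up, so 49.5
#' becomes 50 and 55.7 becomes 56.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# lowercase alphanumeric tokenization; the single tokenizer used everywhere so
# that variant matching and context matching agree on word boundaries.
tokenize <- function(text) {
  toks <- strsplit(tolower(text), "[^a-z0-9]+")
  lapply(toks, function(t) t[nzchar(t)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic integer keys for named counts etc.
sort_by_name <- function(x) x[order(names(x))]
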
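# Independent oracles and tiny builders shared across test files.

# Longest root-to-leaf path, computed independently of tree_depth():
# Bellman-Ford shortest paths on -1 edge weights over the (acyclic) edge list.
depth_oracle <- function(edges, root) {
  if (!nrow(edges)) return(0L)
  g <- igraph::graph_from_data_frame(edges[, c("source", "recipient")],
                                     directed = TRUE)
  d <- igraph::distances(g, v = as.character(root), mode = "out",
                         weights = rep(-1, nrow(edges)),
                         algorithm = "bellman-ford")
  as.integer(-min(d[is.finite(d)]))
}

# naive per-row scan: participants of every thread
participants_oracle <- function(posts) {
  lapply(split(posts$author, posts$thread_id), unique)
}

# quick forum from a compact spec: list of threads, each a character vector of
# authors (posts in order); texts optional via the `texts` list.
quick_forum <- function(threads, texts = NULL) {
  rows <- list()
  k <- 0L
  for (t in seq_along(threads)) {
    for (j in seq_along(threads[[t]])) {
      k <- k + 1L
      txt <- if (!is.null(texts)) texts[[t]][j] else "just a plain update"
      rows[[k]] <- data.frame(thread_id = sprintf("t%03d", t),
                              author = threads[[t]][j], text = txt,
                              stringsAsFactors = FALSE)
    }
  }
  as_forum(do.call(rbind, rows))
}

# full inference chain on a raw forum with the default pattern
infer_forum <- function(forum, pattern = stroke_legacy_pattern(),
                        annotations = NULL, tie_break = "earliest") {
  m <- apply_context_rule(find_candidates(forum, pattern), pattern, forum)
  m <- merge_annotations(m, annotations)
  ad <- detect_adoptions(m)
  ex <- classify_exposure(forum, m, ad, tie_break = tie_break)
  tree <- build_diffusion_tree(forum, m, ex, ad)
  list(mentions = m, adoptions = ad, exposures = ex, tree = tree)
}

# deterministic small config for property sweeps
small_config <- function(seed, ...) {
  args <- list(n_users = 30L, n_threads = 40L, mean_thread_size = 2.5,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}
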
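# Independent oracles for the query layer.

# BFS from every node over an explicit adjacency list: the brute-force
# reachability oracle for the themeOf closure.
bfs_closure <- function(edges) {
  adj <- split(edges$object, edges$subject)
  nodes <- unique(edges$subject)
  out <- list()
  for (n in nodes) {
    seen <- character()
    frontier <- adj[[n]]
    while (length(frontier)) {
      seen <- union(seen, frontier)
      nxt <- unique(unlist(adj[intersect(frontier, names(adj))]))
      frontier <- setdiff(nxt, seen)
    }
    if (length(seen)) out[[n]] <- tibble::tibble(subject = n, object = seen)
  }
  res <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(subject = character(), object = character())
  dplyr::arrange(res, subject, object)
}

# wrap a bare edge list as a graph carrying only themeOf statements
theme_edge_graph <- function(edges, cfg = ns_config()) {
  triple_graph(tibble::tibble(
    subject = edges$subject,
    predicate = paste0(cfg$task, "themeOf"),
    object = edges$object))
}
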
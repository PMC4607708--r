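# Independent shortest-path oracle on the equivalent node-weighted DAG,
# via igraph. Node (r, c) carries the cost of entering it; edges connect
# (r, c) -> (r', c + 1) for |r - r'| <= max_jump. A virtual source pays the
# first column's node costs on its outgoing edges.
oracle_shortest_path <- function(cost, max_jump) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  R <- nrow(cost); C <- ncol(cost)
  id <- function(r, c) (c - 1L) * R + r
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  src <- R * C + 1L
  from <- c(from, rep(src, R)); to <- c(to, id(seq_len(R), 1L))
  wt <- c(wt, cost[, 1L])
  for (c in seq_len(C - 1L)) {
    for (r in seq_len(R)) {
      rr <- max(1L, r - max_jump):min(R, r + max_jump)
      from <- c(from, rep(id(r, c), length(rr)))
      to <- c(to, id(rr, c + 1L))
      wt <- c(wt, cost[rr, c + 1L])
    }
  }
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = TRUE)
  igraph::E(g)$weight <- wt
  d <- igraph::distances(g, v = src, to = id(seq_len(R), C),
                         mode = "out", algorithm = "dijkstra")
  best_end <- which.min(d)
  sp <- igraph::shortest_paths(g, from = src, to = id(best_end, C),
                               mode = "out", output = "vpath")$vpath[[1]]
  nodes <- as.integer(sp)[-1L]  # drop virtual source
  rows <- ((nodes - 1L) %% R) + 1L
  list(rows = rows, cost = min(d))
}

# small, fast phantom for unit tests
small_spec <- function(...) {
  phantom_spec(rows = 200L, n_ascans = 200L, scan_length_mm = 6, ...)
}

mae_path <- function(path, truth) mean(abs(path$rows - truth))
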
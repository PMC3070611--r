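# Independent brute-force oracles. Everything here is written from first
# principles (recursive enumeration, direct counting) and never calls the
# package's own algorithms or igraph.

# adjacency list (named list of character vectors) from an edge data frame
adj_list <- function(edges, vertices) {
  adj <- stats::setNames(vector("list", length(vertices)), vertices)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$source[i]]] <- c(adj[[edges$source[i]]], edges$target[i])
  }
  lapply(adj, unique)
}

# all simple directed paths source -> target, sorted by (hop count, then
# lexicographic vertex sequence) -- the reference ordering for unit weights
enumerate_simple_paths <- function(edges, vertices, source, target) {
  adj <- adj_list(edges, vertices)
  out <- list()
  recurse <- function(path) {
    cur <- path[length(path)]
    if (cur == target) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (nxt in adj[[cur]]) {
      if (!(nxt %in% path)) recurse(c(path, nxt))
    }
  }
  if (source %in% vertices && target %in% vertices) recurse(source)
  if (!length(out)) return(out)
  keys <- vapply(out, paste, character(1), collapse = "\x1f")
  lens <- lengths(out)
  out[order(lens, keys, method = "radix")]
}

# reachability (transitive closure) by repeated boolean squaring
reach_matrix <- function(edges, vertices) {
  n <- length(vertices)
  m <- matrix(FALSE, n, n, dimnames = list(vertices, vertices))
  for (i in seq_len(nrow(edges))) m[edges$source[i], edges$target[i]] <- TRUE
  diag(m) <- TRUE
  repeat {
    m2 <- (m %*% m) > 0
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# scaled betweenness by explicit all-pairs enumeration of shortest paths on
# the simple undirected projection of an edge set
brute_betweenness <- function(edges, vertices) {
  und <- unique(data.frame(
    a = pmin(edges$source, edges$target),
    b = pmax(edges$source, edges$target), stringsAsFactors = FALSE))
  und <- und[und$a != und$b, , drop = FALSE]
  sym <- data.frame(source = c(und$a, und$b), target = c(und$b, und$a),
                    stringsAsFactors = FALSE)
  n <- length(vertices)
  score <- stats::setNames(rep(0, n), vertices)
  if (n < 3) return(score)
  for (s in vertices) for (t in vertices) {
    if (s >= t) next  # unordered pairs once
    paths <- enumerate_simple_paths(sym, vertices, s, t)
    if (!length(paths)) next
    minlen <- min(lengths(paths))
    sps <- paths[lengths(paths) == minlen]
    for (v in vertices) {
      if (v == s || v == t) next
      through <- sum(vapply(sps, function(p) v %in% p, logical(1)))
      score[v] <- score[v] + through / length(sps)
    }
  }
  # unordered-pair sum scaled by 2/((n-1)(n-2)) (Freeman normalization)
  score * 2 / ((n - 1) * (n - 2))
}

brute_degree_centrality <- function(edges, vertices) {
  und <- unique(data.frame(
    a = pmin(edges$source, edges$target),
    b = pmax(edges$source, edges$target), stringsAsFactors = FALSE))
  und <- und[und$a != und$b, , drop = FALSE]
  deg <- stats::setNames(rep(0, length(vertices)), vertices)
  for (i in seq_len(nrow(und))) {
    deg[und$a[i]] <- deg[und$a[i]] + 1
    deg[und$b[i]] <- deg[und$b[i]] + 1
  }
  deg / (length(vertices) - 1)
}

# inverse standard normal CDF of (1 - p) by bisection on pnorm
bisect_inv_norm <- function(p, tol = 1e-12) {
  lo <- -40; hi <- 40
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < 1 - p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
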
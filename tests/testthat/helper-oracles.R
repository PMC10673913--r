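# Independent brute-force oracles for graph and enrichment primitives.
# None of these go through igraph or the package's own implementations.

# Adjacency matrix from an edge data frame over named nodes.
oracle_adj <- function(nodes, edges) {
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      A[edges$from[i], edges$to[i]] <- 1L
      A[edges$to[i], edges$from[i]] <- 1L
    }
  }
  A
}

# All-pairs shortest-path distances by Floyd-Warshall.
oracle_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], "+")
    d <- pmin(d, dk)
  }
  d
}

# Normalized betweenness by exhaustive simple-path enumeration (small n).
oracle_betweenness <- function(A) {
  n <- nrow(A)
  all_paths <- function(from, to) {
    res <- list()
    rec <- function(path) {
      v <- path[length(path)]
      if (v == to) {
        res[[length(res) + 1]] <<- path
        return(invisible())
      }
      for (w in which(A[v, ] > 0)) if (!(w %in% path)) rec(c(path, w))
    }
    rec(from)
    res
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      ps <- all_paths(s, t)
      if (!length(ps)) next
      lens <- lengths(ps)
      sp <- ps[lens == min(lens)]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        onpath <- sum(vapply(sp, function(p) v %in% p, logical(1)))
        btw[v] <- btw[v] + onpath / length(sp)
      }
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# Wasserman-Faust closeness from Floyd-Warshall distances.
oracle_closeness <- function(A) {
  d <- oracle_distances(A)
  n <- nrow(A)
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    fin <- di[is.finite(di)]
    r <- length(fin)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(fin))
  }, numeric(1))
}

# Maximal cliques by exhaustive subset enumeration (n <= ~15).
oracle_cliques <- function(A, min_size = 2L) {
  n <- nrow(A)
  nodes <- rownames(A)
  subsets <- list()
  for (mask in seq_len(2^n - 1)) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(v) < min_size) next
    sub <- A[v, v, drop = FALSE]
    if (all(sub[upper.tri(sub)] == 1)) subsets[[length(subsets) + 1]] <- v
  }
  is_max <- vapply(subsets, function(v) {
    !any(vapply(subsets, function(w)
      length(w) > length(v) && all(v %in% w), logical(1)))
  }, logical(1))
  cl <- lapply(subsets[is_max], function(v) sort(nodes[v]))
  keys <- vapply(cl, paste, character(1), collapse = "|")
  cl[order(-lengths(cl), keys)]
}

# Modularity by the direct double sum over all ordered node pairs.
oracle_modularity <- function(A, membership) {
  deg <- rowSums(A)
  m2 <- sum(deg)
  if (m2 == 0) return(0)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j])
        q <- q + A[i, j] - deg[i] * deg[j] / m2
    }
  }
  unname(q / m2)
}

# Upper-tail hypergeometric probability by explicit pmf summation.
oracle_hyper_upper <- function(k, N, K, n) {
  if (n == 0) return(1)
  js <- k:min(K, n)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Random connected-ish test graph as an edge data frame.
random_edges <- function(n, p, nodes = letters[seq_len(n)]) {
  pairs <- t(combn(nodes, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

graph_from_edges <- function(nodes, edges) {
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}

edge_key_set <- function(edges) {
  if (!nrow(edges)) return(character(0))
  paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|")
}
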
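# Brute-force oracles, independent of the code paths they check.

# Hand-rolled breadth-first distances over the raw edge list (no igraph
# shortest-path machinery), used to cap the exhaustive enumeration below.
bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n); d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- d[frontier[1]] + 1
    frontier <- nxt
  }
  d
}

adj_list <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(el))) {
    adj[[el[k, 1]]] <- c(adj[[el[k, 1]]], el[k, 2])
    adj[[el[k, 2]]] <- c(adj[[el[k, 2]]], el[k, 1])
  }
  adj
}

# All shortest paths between two vertices by exhaustive simple-path
# enumeration (shortest paths are simple, so enumeration bounded by the
# BFS distance is exhaustive).
shortest_paths_enum <- function(g, s, t, cutoff = -1) {
  paths <- igraph::all_simple_paths(g, from = s, to = t, cutoff = cutoff)
  if (!length(paths)) return(list())
  len <- vapply(paths, length, integer(1))
  paths[len == min(len)]
}

# Betweenness by path enumeration, normalized by (n-1)(n-2)/2.
oracle_betweenness <- function(g) {
  n <- igraph::vcount(g)
  adj <- adj_list(g)
  b <- numeric(n)
  for (s in seq_len(n - 1)) for (t in seq(s + 1, n)) {
    ds <- bfs_dist(adj, s)
    if (is.infinite(ds[t])) next
    sp <- shortest_paths_enum(g, s, t, cutoff = ds[t])
    if (!length(sp)) next
    for (p in sp) {
      interior <- setdiff(as.integer(p), c(s, t))
      b[interior] <- b[interior] + 1 / length(sp)
    }
  }
  stats::setNames(b / ((n - 1) * (n - 2) / 2), igraph::V(g)$name)
}

# Closeness per component from hand-rolled breadth-first distances.
oracle_closeness <- function(g) {
  n <- igraph::vcount(g)
  adj <- adj_list(g)
  d <- t(vapply(seq_len(n), function(s) bfs_dist(adj, s), numeric(n)))
  vapply(seq_len(n), function(i) {
    reach <- setdiff(which(is.finite(d[i, ])), i)
    if (!length(reach)) return(NA_real_)
    length(reach) / sum(d[i, reach])
  }, numeric(1))
}

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  res <- vector("list", 0)
  rec <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) { res[[length(res) + 1L]] <<- labels; return(invisible()) }
    for (l in seq_len(k + 1L)) rec(c(labels, l), max(k, l))
  }
  rec(integer(0), 0L)
  res
}

# Newman-Girvan Q straight from its definition, sum_c (e_cc - a_c^2).
oracle_q <- function(g, labels) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  if (m == 0) return(0)
  q <- 0
  for (c in unique(labels)) {
    inc <- labels[el[, 1]] == c | labels[el[, 2]] == c
    within <- labels[el[, 1]] == c & labels[el[, 2]] == c
    e_cc <- sum(within) / m
    a_c <- (2 * sum(within) + sum(inc & !within)) / (2 * m)
    q <- q + e_cc - a_c^2
  }
  q
}

# Exhaustive maximum modularity over every set partition (<= 8 nodes).
oracle_max_q <- function(g) {
  parts <- all_partitions(igraph::vcount(g))
  max(vapply(parts, function(lab) oracle_q(g, lab), numeric(1)))
}

# Random connected G(n, p) graph, retrying until connected.
random_connected_graph <- function(n, seed) {
  set.seed(seed)
  repeat {
    p <- stats::runif(1, 0.3, 0.8)
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# Small deterministic correlation_set for network toys.
toy_corr <- function(df, trait_names = sort(unique(c(df$trait_a, df$trait_b)))) {
  attr(df, "traits") <- trait_names
  class(df) <- c("correlation_set", "data.frame")
  df
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
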
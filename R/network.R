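#' Build the significance-thresholded trait network
#'
#' Traits become nodes; an undirected edge joins two traits whenever their
#' pairwise correlation is significant (`p < alpha`). Each edge stores the
#' signed correlation `r`, its magnitude as `weight`, and `sign`. Traits
#' without any significant correlation remain as isolated nodes; an empty
#' graph is allowed.
#'
#' @param corr a `correlation_set` from [pearson_pairwise()].
#' @param alpha edge significance threshold (default 0.05).
#' @return An undirected [igraph::igraph] with vertex attribute `name` and
#'   edge attributes `r`, `weight` (= `|r|`) and `sign` (`"+"`/`"-"`).
#' @export
build_network <- function(corr, alpha = 0.05) {
  stopifnot(inherits(corr, "correlation_set"))
  if (!(alpha > 0 && alpha <= 1)) stop("alpha must be in (0,1]")
  tn <- attr(corr, "traits")
  if (length(tn) < 2) stop("need at least 2 traits")
  keep <- !is.na(corr$p) & corr$p < alpha
  edges <- corr[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$trait_a, to = edges$trait_b,
               r = edges$r, weight = abs(edges$r),
               sign = ifelse(edges$r >= 0, "+", "-")),
    directed = FALSE,
    vertices = data.frame(name = tn))
  g
}

#' Normalized degree centrality
#'
#' Degree divided by `n - 1`, the number of traits a trait could possibly be
#' linked to, so values are comparable across networks of different size.
#'
#' @param net an undirected igraph.
#' @return Named numeric vector in `[0, 1]`.
#' @export
degree_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 2) stop("need at least 2 nodes")
  igraph::degree(net) / (n - 1)
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness on the unweighted (topological) graph —
#' correlation magnitudes are similarities, not path costs — divided by
#' `(n-1)(n-2)/2`, the number of node pairs that could route through a
#' node.
#'
#' @param net an undirected igraph with at least 3 nodes.
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(net) {
  n <- igraph::vcount(net)
  if (n < 3) stop("betweenness undefined for fewer than 3 nodes")
  igraph::betweenness(net, directed = FALSE, weights = NA) /
    ((n - 1) * (n - 2) / 2)
}

#' Closeness centrality within connected components
#'
#' For a node i in a connected component of size `n_c >= 2`,
#' `(n_c - 1) / sum_j d(i, j)` over unweighted shortest-path distances to
#' the other members of its component. Isolated nodes are undefined (`NA`).
#'
#' @param net an undirected igraph.
#' @return A data.frame with `trait`, `closeness` (in `(0, 1]`, `NA` for
#'   isolated nodes) and `component` id.
#' @export
closeness_centrality <- function(net) {
  comp <- igraph::components(net)$membership
  d <- igraph::distances(net, weights = NA)
  cl <- vapply(seq_along(comp), function(i) {
    members <- which(comp == comp[i])
    if (length(members) < 2) return(NA_real_)
    (length(members) - 1) / sum(d[i, setdiff(members, i)])
  }, numeric(1))
  data.frame(trait = vertex_names(net), closeness = cl,
             component = unname(comp), row.names = NULL)
}

#' All three centrality metrics in one table
#'
#' @param net an undirected igraph with >= 3 nodes.
#' @return A data.frame with `trait`, `degree`, `betweenness`, `closeness`,
#'   `component`.
#' @export
centrality_table <- function(net) {
  cl <- closeness_centrality(net)
  data.frame(trait = cl$trait,
             degree = unname(degree_centrality(net)),
             betweenness = unname(betweenness_centrality(net)),
             closeness = cl$closeness,
             component = cl$component, row.names = NULL)
}

#' Newman-Girvan modularity of a labelled partition
#'
#' `Q = sum_modules (e_ii - a_i^2)`: the fraction of edges inside modules
#' minus its expectation under a degree-preserving random graph. Unweighted
#' by default (each edge counts 1) so small-graph brute-force checks are
#' exact; `weighted = TRUE` uses the edge `weight` attribute.
#'
#' @param net an undirected igraph.
#' @param membership integer module label per node (0-based or any
#'   contiguous coding), named or in vertex order; every node must be
#'   labelled.
#' @param weighted use `|r|` edge weights.
#' @return Modularity Q.
#' @export
modularity_score <- function(net, membership, weighted = FALSE) {
  v <- vertex_names(net)
  if (!is.null(names(membership))) {
    if (!all(v %in% names(membership)))
      stop("unlabeled node(s): ",
           paste(setdiff(v, names(membership)), collapse = ", "))
    membership <- membership[v]
  } else if (length(membership) != length(v)) {
    stop("membership must label every node")
  }
  if (anyNA(membership)) stop("unlabeled node(s) (NA labels)")
  w <- if (weighted) igraph::E(net)$weight else rep(1, igraph::ecount(net))
  igraph::modularity(net, as.integer(membership) -
                       min(as.integer(membership)) + 1L, weights = w)
}

#' Trait modules by spin-glass simulated annealing
#'
#' Minimises the Potts spin-glass energy (configuration null model,
#' resolution `gamma`) by simulated annealing, the stochastic community
#' search behind optimal-modularity partitions. The annealer is run
#' `n_runs` times per connected component with seeded starts and the best
#' partition (highest modularity of the induced labels) is kept; per-run
#' modularities are returned as diagnostics. Components are partitioned
#' independently (with a warning when the graph is disconnected) and their
#' label blocks concatenated; singleton components get their own module.
#'
#' @param net an undirected igraph; edge weights (`|r|`) are used by the
#'   annealer. For graphs with negative correlations set
#'   `implementation = "neg"` to use the signed Hamiltonian (requires a
#'   signed `weight` attribute).
#' @param spins maximum number of modules (default 25).
#' @param gamma resolution parameter (default 1).
#' @param start_temp,stop_temp,cool_fact annealing schedule (defaults 1,
#'   0.01, 0.99).
#' @param n_runs number of seeded annealer restarts kept best-of (default 10).
#' @param seed integer seed; run i uses `sub_seed(seed, paste0("run", i))`.
#' @param implementation `"orig"` (default) or `"neg"` (signed Hamiltonian).
#' @return A list of class `trait_partition`: `membership` (named integer
#'   labels from 0), `Q` (unweighted modularity of the returned labels),
#'   `runs` (per-run Q diagnostics), `params`, `seed`.
#' @export
spinglass_partition <- function(net, spins = 25, gamma = 1,
                                start_temp = 1, stop_temp = 0.01,
                                cool_fact = 0.99, n_runs = 10, seed = 1,
                                implementation = c("orig", "neg")) {
  implementation <- match.arg(implementation)
  comp <- igraph::components(net)
  if (comp$no > 1)
    warning("graph is disconnected; partitioning each component separately")
  membership <- stats::setNames(rep(NA_integer_, igraph::vcount(net)),
                                vertex_names(net))
  next_label <- 0L
  run_q <- list()
  for (ci in seq_len(comp$no)) {
    nodes <- which(comp$membership == ci)
    if (length(nodes) <= 2) {
      # singleton, or a lone edge: one module is trivially optimal and the
      # annealer has nothing to search
      membership[nodes] <- next_label
      next_label <- next_label + 1L
      next
    }
    sub <- igraph::induced_subgraph(net, nodes)
    best <- NULL; best_q <- -Inf; qs <- numeric(n_runs)
    for (i in seq_len(n_runs)) {
      cm <- with_seed(sub_seed(seed, paste0("component", ci, "run", i)),
                      igraph::cluster_spinglass(
                        sub, spins = min(spins, igraph::vcount(sub)),
                        gamma = gamma, start.temp = start_temp,
                        stop.temp = stop_temp, cool.fact = cool_fact,
                        implementation = implementation))
      q <- modularity_score(sub, igraph::membership(cm))
      qs[i] <- q
      if (q > best_q) { best_q <- q; best <- igraph::membership(cm) }
    }
    run_q[[ci]] <- qs
    labs <- as.integer(factor(best)) - 1L
    membership[nodes] <- labs + next_label
    next_label <- next_label + max(labs) + 1L
  }
  structure(list(membership = membership,
                 Q = modularity_score(net, membership),
                 runs = run_q,
                 params = list(spins = spins, gamma = gamma,
                               start_temp = start_temp,
                               stop_temp = stop_temp, cool_fact = cool_fact,
                               n_runs = n_runs,
                               implementation = implementation),
                 seed = seed),
            class = "trait_partition")
}

#' @export
print.trait_partition <- function(x, ...) {
  cat(sprintf("trait_partition: %d modules, Q = %.4f\n",
              length(unique(x$membership)), x$Q))
  for (m in sort(unique(x$membership)))
    cat(sprintf("  module %d: %s\n", m,
                paste(names(x$membership)[x$membership == m], collapse = ", ")))
  invisible(x)
}

#' Write a trait network to GraphML or edge-list CSV
#'
#' @param net an igraph network from [build_network()].
#' @param path output path; format chosen by extension (`.graphml` or
#'   `.csv`).
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    df <- igraph::as_data_frame(net, what = "edges")
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
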
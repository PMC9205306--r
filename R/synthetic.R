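#' Simulate a pure-birth phylogeny
#'
#' Generates a binary rooted tree under a Yule (pure-birth) process with all
#' branch lengths positive, as a stand-in for a community phylogeny. Tip
#' labels are `sp01`, `sp02`, ...
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed; the same `(n_tips, seed)` pair always yields the
#'   identical tree (identical Newick string).
#' @return An [ape::ape-package] `phylo` object, rooted and binary.
#' @export
simulate_tree <- function(n_tips, seed = 1) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  n_tips <- as.integer(n_tips)
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
  tree
}

#' Specification of a synthetic two-module trait community
#'
#' Describes the generative model used by [simulate_traits()]:
#' \deqn{x_{st} = \beta_t \log_{10} B_s + BM_t(s;\sigma_{BM})
#'       + \lambda_t f_{m(t),s} + \epsilon_{st}}
#' where \eqn{B_s} is log-normal total biomass (median 1),
#' \eqn{BM_t} an independent Brownian-motion realisation on the phylogeny,
#' \eqn{f_{m,s}} iid standard-normal module factors shared by all traits of
#' module \eqn{m}, and \eqn{\epsilon} iid Gaussian noise. Within one module
#' the population trait-trait correlation is
#' \eqn{\lambda^2 / (\lambda^2 + \sigma_\epsilon^2)} when `sigma_bm` and
#' `beta` are zero.
#'
#' @param n_species number of species (tree tips).
#' @param traits character vector of trait names.
#' @param modules integer module membership per trait (same length as
#'   `traits`); each trait belongs to exactly one module.
#' @param lambda factor loading(s) >= 0, recycled over traits.
#' @param sigma_eps residual standard deviation > 0.
#' @param sigma_bm Brownian-motion rate >= 0 (per unit branch length).
#' @param beta allometric slope(s) of trait on log10 biomass, recycled.
#' @param sigma_logb standard deviation of log10 biomass.
#' @param missing_species character vector of species ids (or, before the
#'   tree is known, 1-based species indices) whose `missing_traits` cells
#'   are blanked.
#' @param missing_traits character vector of trait names to blank for
#'   `missing_species`.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_species,
                           traits = c("SLA", "MPU", "LTh", "LWC", "WD",
                                      "SWC", "SRL", "MRD", "RTh", "RD"),
                           modules = rep(c(1L, 2L), length.out = length(traits)),
                           lambda = 1.25, sigma_eps = 1, sigma_bm = 0.3,
                           beta = 0.3, sigma_logb = 0.5,
                           missing_species = character(),
                           missing_traits = character()) {
  stopifnot(n_species >= 2, length(traits) >= 1,
            length(modules) == length(traits))
  lambda <- rep_len(lambda, length(traits))
  beta <- rep_len(beta, length(traits))
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (sigma_eps <= 0) stop("sigma_eps must be > 0")
  if (sigma_bm < 0) stop("sigma_bm must be >= 0")
  if (anyDuplicated(traits)) stop("trait names must be unique")
  if (!all(missing_traits %in% traits))
    stop("missing_traits refers to unknown traits")
  structure(list(n_species = as.integer(n_species), traits = traits,
                 modules = as.integer(modules), lambda = lambda,
                 sigma_eps = sigma_eps, sigma_bm = sigma_bm, beta = beta,
                 sigma_logb = sigma_logb,
                 missing_species = missing_species,
                 missing_traits = missing_traits),
            class = "synthetic_spec")
}

#' Preset synthetic communities mirroring the two study designs
#'
#' `spec_dry_forest()` emulates a seasonally dry forest design: 52 species
#' with leaf and stem traits, root traits (`SRL`, `MRD`, `RTh`, `RD`)
#' measured for only 28 of them (a block of 24 species is blanked).
#' `spec_moist_forest()` emulates a moist forest design: 43 species with all
#' 10 traits complete. Both plant two trait modules.
#'
#' @param ... overrides passed on to [synthetic_spec()].
#' @return A `synthetic_spec`.
#' @export
spec_dry_forest <- function(...) {
  root <- c("SRL", "MRD", "RTh", "RD")
  trts <- c("SLA", "MPU", "LTh", "LWC", "WD", "SWC", root)
  args <- list(n_species = 52, traits = trts,
               modules = c(1L, 1L, 1L, 1L, 1L, 1L, 2L, 1L, 2L, 2L),
               missing_species = sprintf("sp%02d", 29:52),
               missing_traits = root)
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

#' @rdname spec_dry_forest
#' @export
spec_moist_forest <- function(...) {
  args <- list(n_species = 43,
               modules = c(2L, 1L, 1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L))
  args[names(list(...))] <- list(...)
  do.call(synthetic_spec, args)
}

#' Simulate a species-mean trait table with known ground truth
#'
#' Draws trait values under the factor + Brownian + allometry model of
#' [synthetic_spec()] on a given phylogeny, blanks the configured missing
#' block, and returns a [trait_table()] whose `ground_truth` attribute
#' records the module map and every generating parameter.
#'
#' @param tree a `phylo` object; its tip count must equal `spec$n_species`.
#' @param spec a `synthetic_spec`.
#' @param seed integer seed.
#' @param site site label stored on the table.
#' @return A `trait_table` with a `ground_truth` attribute.
#' @export
simulate_traits <- function(tree, spec, seed = 1, site = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  n <- length(tree$tip.label)
  if (n != spec$n_species)
    stop("tree has ", n, " tips but spec expects ", spec$n_species)
  p <- length(spec$traits)
  with_seed(seed, {
    log10_b <- stats::rnorm(n, 0, spec$sigma_logb)   # log-normal biomass, median 1
    biomass <- 10^log10_b
    n_mod <- max(spec$modules)
    f <- matrix(stats::rnorm(n_mod * n), n_mod, n)   # module factors
    x <- matrix(NA_real_, n, p, dimnames = list(tree$tip.label, spec$traits))
    for (j in seq_len(p)) {
      bm <- if (spec$sigma_bm > 0)
        ape::rTraitCont(tree, model = "BM", sigma = spec$sigma_bm,
                        root.value = 0)
      else stats::setNames(rep(0, n), tree$tip.label)
      x[, j] <- spec$beta[j] * log10_b + bm[tree$tip.label] +
        spec$lambda[j] * f[spec$modules[j], ] +
        stats::rnorm(n, 0, spec$sigma_eps)
    }
    miss_sp <- spec$missing_species
    if (is.numeric(miss_sp)) miss_sp <- tree$tip.label[miss_sp]
    if (length(miss_sp) && !all(miss_sp %in% tree$tip.label))
      stop("missing_species refers to species absent from the tree")
    x[miss_sp, spec$missing_traits] <- NA_real_
    out <- trait_table(x, site = site, biomass = biomass)
    attr(out, "ground_truth") <- list(
      modules = stats::setNames(spec$modules, spec$traits),
      spec = spec, seed = seed, log10_biomass = log10_b)
    out
  })
}

#' Generate a planted-partition benchmark graph
#'
#' Nodes are split into `n_modules` groups; each within-group pair is linked
#' with probability `p_in` and each between-group pair with probability
#' `p_out < p_in`. Used to benchmark the community-detection stage against a
#' known ground truth. When `n_modules` does not divide `n_nodes` the
#' remainder is spread one node at a time over the first modules.
#'
#' @param n_nodes total number of nodes.
#' @param n_modules number of planted modules.
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability; must be `< p_in`.
#' @param seed integer seed.
#' @return A list with `graph` (undirected [igraph::igraph] with unit
#'   weights) and `membership` (integer ground-truth labels from 0).
#' @export
make_planted_network <- function(n_nodes, n_modules, p_in, p_out, seed = 1) {
  stopifnot(n_nodes >= 2, n_modules >= 1)
  if (!(p_out >= 0 && p_in <= 1 && p_out < p_in))
    stop("require 0 <= p_out < p_in <= 1: no recoverable structure otherwise")
  sizes <- rep(n_nodes %/% n_modules, n_modules) +
    c(rep(1L, n_nodes %% n_modules), rep(0L, n_modules - n_nodes %% n_modules))
  membership <- rep(seq_len(n_modules) - 1L, times = sizes)
  pairs <- utils::combn(n_nodes, 2)
  prob <- ifelse(membership[pairs[1, ]] == membership[pairs[2, ]], p_in, p_out)
  keep <- with_seed(seed, stats::runif(length(prob)) < prob)
  g <- igraph::make_empty_graph(n_nodes, directed = FALSE)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n_nodes))
  g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
  igraph::E(g)$weight <- 1
  igraph::V(g)$true_module <- membership
  list(graph = g, membership = stats::setNames(membership, igraph::V(g)$name))
}

#' @rdname make_planted_network
#' @param x result of `make_planted_network()` (or any igraph graph).
#' @param path output file for a two/three-column edge list CSV.
#' @export
write_edge_list <- function(x, path) {
  g <- if (is.list(x) && !igraph::is_igraph(x)) x$graph else x
  df <- igraph::as_data_frame(g, what = "edges")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
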
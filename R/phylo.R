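#' Prepare a phylogeny for independent contrasts
#'
#' Applies the tree conventions used throughout the pipeline: tips absent
#' from the trait table are pruned (with a warning), every polytomy is
#' replaced by a random dichotomous resolution (seeded, so reproducible),
#' and then all branch lengths are set to 1. The resolution step inserts
#' zero-length branches which the global set-lengths-to-1 step overwrites —
#' resolve first, unit lengths second.
#'
#' @param tree a rooted `phylo` object; polytomies allowed, branch lengths
#'   optional.
#' @param species optional character vector of species that must be on the
#'   tree (typically the trait table's species). Species missing from the
#'   tree are an error listing them; extra tips are pruned with a warning.
#' @param seed integer seed for the random polytomy resolution.
#' @return A binary rooted `phylo` with all branch lengths equal to 1.
#' @export
prepare_tree <- function(tree, species = NULL, seed = 1) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  # the basal node is taken as the root (a star tree is a legal input)
  if (!is.null(species)) {
    absent <- setdiff(species, tree$tip.label)
    if (length(absent))
      stop("species absent from tree: ", paste(absent, collapse = ", "))
    extra <- setdiff(tree$tip.label, species)
    if (length(extra)) {
      warning("pruning ", length(extra), " tip(s) not in the trait table")
      tree <- ape::drop.tip(tree, extra)
    }
  }
  tree <- with_seed(seed, ape::multi2di(tree, random = TRUE))
  tree$edge.length <- rep(1, nrow(tree$edge))
  tree
}

#' Phylogenetically independent contrasts for one trait
#'
#' Standard pruning-algorithm contrasts: at each internal node joining
#' daughters i and j the contrast is `(x_i - x_j) / sqrt(b_i + b_j)`, the
#' ancestral value is the 1/b-weighted mean of the daughters, and the
#' ancestor's branch is lengthened by `b_i b_j / (b_i + b_j)`. A binary tree
#' with S tips yields S - 1 contrasts.
#'
#' @param tree binary rooted `phylo` with positive branch lengths (run
#'   [prepare_tree()] first if needed).
#' @param x named numeric vector of tip values (names = tip labels), or
#'   unnamed in tip order; must be complete (prune missing tips first).
#' @return A data.frame with one row per internal node: `contrast` and the
#'   expected `variance` (sum of adjusted daughter branch lengths).
#' @export
pic_contrasts <- function(tree, x) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo' object")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree has unresolved polytomies or no root; run prepare_tree() first")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (is.null(names(x))) names(x) <- tree$tip.label
  if (anyNA(x)) stop("tip values must be complete; prune missing tips first")
  pc <- ape::pic(x, tree, scaled = TRUE, var.contrasts = TRUE)
  data.frame(node = as.integer(rownames(pc)), contrast = pc[, "contrasts"],
             variance = pc[, "variance"], row.names = NULL)
}

#' Contrast matrix across traits
#'
#' Restricts the table to species complete for all requested traits, prunes
#' the tree to those species, and computes contrasts per trait on that one
#' shared tree, so contrasts are aligned by internal node across traits and
#' can be fed to correlation or PCA exactly like ordinary observations.
#'
#' @param tree binary rooted `phylo` covering the table's species (extra
#'   tips are pruned).
#' @param table a [trait_table()] (or numeric matrix with species rownames).
#' @param traits traits to include; default all.
#' @return A matrix of contrasts, one row per internal node of the pruned
#'   tree, one column per trait; its `tree` attribute is the pruned tree.
#' @export
pic_matrix <- function(tree, table, traits = NULL) {
  x <- if (inherits(table, "trait_table")) table$values else as.matrix(table)
  if (!is.null(traits)) x <- x[, traits, drop = FALSE]
  keep <- stats::complete.cases(x)
  if (sum(keep) < 4)
    stop("fewer than 4 species complete for the requested traits")
  x <- x[keep, , drop = FALSE]
  absent <- setdiff(rownames(x), tree$tip.label)
  if (length(absent))
    stop("species absent from tree: ", paste(absent, collapse = ", "))
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, rownames(x)))
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("tree has unresolved polytomies or no root; run prepare_tree() first")
  out <- vapply(colnames(x),
                function(tn) pic_contrasts(tree, x[tree$tip.label, tn])$contrast,
                numeric(tree$Nnode))
  rownames(out) <- as.character(seq_len(tree$Nnode) + length(tree$tip.label))
  attr(out, "tree") <- tree
  out
}

#' Pairwise correlations of independent contrasts
#'
#' By default contrasts are treated as ordinary observations (centred
#' Pearson correlation), the form that feeds the standard PCA downstream.
#' `through_origin = TRUE` gives the methodologically strict alternative in
#' which contrast products are not centred (contrasts have expectation zero
#' under Brownian evolution and an arbitrary sign).
#'
#' @param contrasts matrix from [pic_matrix()].
#' @param through_origin force the correlation through the origin.
#' @return A `correlation_set` as from [pearson_pairwise()].
#' @export
pic_correlations <- function(contrasts, through_origin = FALSE) {
  if (!through_origin) return(pearson_pairwise(contrasts))
  tn <- colnames(contrasts)
  pairs <- utils::combn(ncol(contrasts), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    u <- contrasts[, pairs[1, k]]; v <- contrasts[, pairs[2, k]]
    n <- length(u)
    r <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
    # origin-constrained r: t test on n - 1 df (no mean estimated)
    tstat <- r * sqrt(n - 1) / sqrt(max(1 - r^2, 0))
    data.frame(trait_a = tn[pairs[1, k]], trait_b = tn[pairs[2, k]],
               r = r, n = n, p = 2 * stats::pt(-abs(tstat), df = n - 1))
  })
  out <- do.call(rbind, rows)
  attr(out, "traits") <- tn
  class(out) <- c("correlation_set", "data.frame")
  out
}
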
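#' Principal component analysis with a deterministic sign convention
#'
#' Eigen-decomposition of the correlation matrix (`standardize = TRUE`, the
#' default and the only defensible choice for mixed-unit trait data) or the
#' covariance matrix. Complete cases only. Because eigenvector signs are
#' arbitrary, every component is oriented so that the loading of the first
#' variable (alphabetically) with a nonzero loading on it is positive,
#' making results reproducible across linear-algebra backends.
#'
#' @param x numeric matrix or data.frame, observations x variables (>= 2
#'   complete observations, >= 2 variables).
#' @param standardize scale variables to unit variance (correlation-matrix
#'   PCA) rather than covariance-matrix PCA.
#' @return A list of class `pca_result`: `loadings` (variables x
#'   components), `scores` (observations x components), `variance_fraction`
#'   (non-increasing, sums to 1), `standardize`.
#' @export
pca <- function(x, standardize = TRUE) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2 || ncol(x) < 2)
    stop("need at least 2 complete observations and 2 variables")
  if (standardize) {
    sds <- apply(x, 2, stats::sd)
    if (any(sds == 0))
      stop("constant variable(s) under standardization: ",
           paste(colnames(x)[sds == 0], collapse = ", "))
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  loadings <- fit$rotation
  scores <- fit$x
  ord <- order(colnames(x))
  for (j in seq_len(ncol(loadings))) {
    lead <- ord[which(abs(loadings[ord, j]) > 1e-12)[1]]
    if (!is.na(lead) && loadings[lead, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = fit$sdev^2 / sum(fit$sdev^2),
                 standardize = standardize),
            class = "pca_result")
}

#' Trait importance as PC1 of the three centrality metrics
#'
#' Summarises degree, betweenness and closeness into a single importance
#' value per trait: the first principal component of the standardized
#' (correlation-matrix) PCA of the three metrics, sign-oriented so that the
#' degree loading is positive — high scores mean well-connected hub traits.
#'
#' @param centralities data.frame from [centrality_table()] (columns
#'   `trait`, `degree`, `betweenness`, `closeness`); rows with undefined
#'   metrics are dropped. At least 4 complete traits required.
#' @return A list of class `importance_result`: `scores` (named per-trait
#'   PC1 values), `variance_fraction` (of PC1), `loadings` (of the three
#'   metrics on PC1), `n`.
#' @export
importance_scores <- function(centralities) {
  need <- c("trait", "degree", "betweenness", "closeness")
  if (!all(need %in% names(centralities)))
    stop("centralities must have columns: ", paste(need, collapse = ", "))
  m <- centralities[stats::complete.cases(
    centralities[, c("degree", "betweenness", "closeness")]), ]
  if (nrow(m) < 4) stop("need at least 4 traits with all three metrics")
  x <- as.matrix(m[, c("degree", "betweenness", "closeness")])
  rownames(x) <- m$trait
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant metric(s) across traits: ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  fit <- pca(x, standardize = TRUE)
  s <- fit$scores[, 1]
  l <- fit$loadings[, 1]
  if (l["degree"] < 0) { s <- -s; l <- -l }
  structure(list(scores = stats::setNames(s, m$trait),
                 variance_fraction = fit$variance_fraction[1],
                 loadings = l, n = nrow(m)),
            class = "importance_result")
}

#' @export
print.importance_result <- function(x, ...) {
  cat(sprintf("importance_result: PC1 of 3 centrality metrics over %d traits\n",
              x$n))
  cat(sprintf("  PC1 variance fraction: %.3f\n", x$variance_fraction))
  print(round(sort(x$scores, decreasing = TRUE), 3))
  invisible(x)
}

#' Compare trait importance between two sites
#'
#' Pearson correlation of the PC1 importance scores of the traits shared by
#' two sites, with the two-sided t-test p-value. Both `r` and `r^2` are
#' reported: the PCA orientation convention affects the sign of `r` but not
#' its magnitude.
#'
#' @param a,b `importance_result` objects; traits matched by name (>= 4
#'   shared required).
#' @return A list with `r`, `r2`, `p`, `n` and the shared `traits`.
#' @export
compare_importance <- function(a, b) {
  stopifnot(inherits(a, "importance_result"), inherits(b, "importance_result"))
  shared <- intersect(names(a$scores), names(b$scores))
  if (length(shared) < 4) stop("fewer than 4 shared traits")
  r <- stats::cor(a$scores[shared], b$scores[shared])
  list(r = r, r2 = r^2, p = pearson_p(r, length(shared)),
       n = length(shared), traits = shared)
}
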
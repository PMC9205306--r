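#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact t transform `t = r * sqrt(n-2) / sqrt(1-r^2)` on `n - 2`
#' degrees of freedom.
#'
#' @param r Pearson correlation coefficient(s).
#' @param n sample size(s), `>= 3`.
#' @return Two-sided p-value(s).
#' @export
pearson_p <- function(r, n) {
  if (any(n < 3)) stop("n must be >= 3")
  if (any(abs(r) > 1)) stop("|r| must be <= 1")
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  2 * stats::pt(-abs(tstat), df = n - 2)
}

#' Pairwise-complete Pearson correlations with per-pair sample sizes
#'
#' For every unordered trait pair, computes the Pearson correlation over the
#' species where both traits are observed (pairwise-complete deletion — not
#' listwise: with block-missing root traits, leaf-stem pairs keep the full
#' species set while root-root pairs use only the root-measured subset) and
#' the two-sided p-value from the t transform. Pairs with fewer than 3
#' complete rows, or zero variance in a pairwise-complete column, are
#' reported undefined (`NA`) with a warning for the latter.
#'
#' @param table a [trait_table()] or a numeric species x traits matrix.
#' @param adjust p-value adjustment across pairs: `"none"` (default,
#'   matching raw `p < 0.05` edge thresholds) or any method of
#'   [stats::p.adjust()] such as `"holm"`.
#' @return A data.frame of class `correlation_set` with columns `trait_a`,
#'   `trait_b`, `r`, `n`, `p`, one row per unordered pair; the `traits`
#'   attribute preserves the full trait list.
#' @export
pearson_pairwise <- function(table, adjust = "none") {
  x <- if (inherits(table, "trait_table")) table$values else as.matrix(table)
  if (ncol(x) < 2) stop("need at least 2 traits")
  tn <- colnames(x)
  pairs <- utils::combn(ncol(x), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    ok <- stats::complete.cases(x[, c(i, j)])
    n <- sum(ok)
    if (n < 3)
      return(data.frame(trait_a = tn[i], trait_b = tn[j],
                        r = NA_real_, n = n, p = NA_real_))
    xi <- x[ok, i]; xj <- x[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warning("zero variance in pair ", tn[i], "-", tn[j], "; undefined")
      return(data.frame(trait_a = tn[i], trait_b = tn[j],
                        r = NA_real_, n = n, p = NA_real_))
    }
    r <- stats::cor(xi, xj)
    data.frame(trait_a = tn[i], trait_b = tn[j], r = r, n = n,
               p = pearson_p(r, n))
  })
  out <- do.call(rbind, rows)
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  attr(out, "traits") <- tn
  class(out) <- c("correlation_set", "data.frame")
  out
}

#' Matrix view of a correlation set
#'
#' @param corr a `correlation_set`.
#' @param what `"r"`, `"p"` or `"n"`.
#' @return A symmetric traits x traits matrix; the diagonal is 1 for `"r"`,
#'   0 for `"p"` and `NA` for `"n"`.
#' @export
correlation_matrix <- function(corr, what = c("r", "p", "n")) {
  what <- match.arg(what)
  tn <- attr(corr, "traits")
  m <- matrix(NA_real_, length(tn), length(tn), dimnames = list(tn, tn))
  idx_a <- match(corr$trait_a, tn); idx_b <- match(corr$trait_b, tn)
  m[cbind(idx_a, idx_b)] <- corr[[what]]
  m[cbind(idx_b, idx_a)] <- corr[[what]]
  diag(m) <- switch(what, r = 1, p = 0, n = NA_real_)
  m
}

#' Fisher r-to-z test for the difference of two independent correlations
#'
#' Tests whether the same trait pair correlates differently at two sites:
#' \deqn{Z = \frac{\mathrm{atanh}(r_1) - \mathrm{atanh}(r_2)}
#'       {\sqrt{1/(n_1-3) + 1/(n_2-3)}}}
#' with a two-sided standard-normal p-value. Z is antisymmetric under
#' swapping the sites; p is unchanged.
#'
#' @param r1,r2 Pearson correlations at each site, `|r| < 1`.
#' @param n1,n2 sample sizes at each site, `>= 4`.
#' @return A data.frame with `r1`, `n1`, `r2`, `n2`, `Z`, `p` (vectorised).
#' @export
compare_correlations <- function(r1, n1, r2, n2) {
  if (any(n1 < 4) || any(n2 < 4)) stop("sample sizes must be >= 4")
  if (any(abs(r1) >= 1) || any(abs(r2) >= 1))
    stop("|r| must be < 1 (z transform is infinite at |r| = 1)")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  data.frame(r1 = r1, n1 = n1, r2 = r2, n2 = n2, Z = z,
             p = 2 * stats::pnorm(-abs(z)))
}
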
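#' One- or two-sided Wilcoxon signed-rank test for paired data
#'
#' Zero differences are dropped (with a message) following the common
#' convention. Tie-free samples with fewer than 50 nonzero differences use
#' the exact distribution over all 2^n sign assignments; ties fall back to
#' midranks with a continuity-corrected normal approximation.
#'
#' @param x Paired differences, or the first member of each pair if `y`
#'   is given.
#' @param y Optional second member of each pair (`x - y` is tested).
#' @param alternative `"greater"`, `"less"`, or `"two.sided"`.
#' @return List of class `td_test`: `statistic` (V), `p`, `alternative`,
#'   `method`, `n` (nonzero differences used).
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (any(!is.finite(d))) stop("non-finite differences")
  n_zero <- sum(d == 0)
  if (n_zero) {
    message("dropping ", n_zero, " zero difference(s)")
    d <- d[d != 0]
  }
  if (!length(d)) stop("all differences are zero; signed-rank test undefined")
  ties <- anyDuplicated(abs(d)) > 0
  exact <- !ties && length(d) < 50
  ht <- suppressWarnings(
    stats::wilcox.test(d, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                 alternative = alternative,
                 method = if (exact) "signed_rank_exact" else "signed_rank_normal",
                 n = length(d)),
            class = "td_test")
}

#' One- or two-sided Wilcoxon rank-sum test for unpaired data
#'
#' Tie-free small samples use the exact rank-sum distribution; otherwise
#' a continuity-corrected normal approximation with the usual tie
#' correction is used.
#'
#' @param x,y Numeric value vectors for the two groups.
#' @param alternative `"greater"` (x tends larger), `"less"`, or
#'   `"two.sided"`.
#' @return List of class `td_test`: `statistic` (W), `p`, `alternative`,
#'   `method`, `n` (c(n_x, n_y)).
#' @export
wilcoxon_rank_sum <- function(x, y,
                              alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  if (any(!is.finite(c(x, y)))) stop("non-finite values")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) < 50 && length(y) < 50
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                       correct = TRUE)
  )
  structure(list(statistic = unname(ht$statistic), p = ht$p.value,
                 alternative = alternative,
                 method = if (exact) "rank_sum_exact" else "rank_sum_normal",
                 n = c(length(x), length(y))),
            class = "td_test")
}

#' @export
print.td_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %g, p = %g (%s)\n",
              x$method, x$statistic, x$p, x$alternative))
  invisible(x)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p Vector of p-values in \[0, 1\] (NAs preserved).
#' @return Adjusted p-values, capped at 1, in the input order.
#' @export
bh_fdr <- function(p) {
  pp <- p[!is.na(p)]
  if (any(pp < 0 | pp > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Empirical p-value from a null sample
#'
#' `(r + 1) / (n + 1)` where `r` counts null values at least as large as
#' the observed value, the standard positively-biased estimator that can
#' never return 0.
#'
#' @param observed Scalar observed statistic (or vector, vectorized over
#'   observations against the same null).
#' @param null Numeric vector of null statistics.
#' @return Empirical p-value(s) in `[1/(n+1), 1]`.
#' @export
empirical_pvalue <- function(observed, null) {
  null <- null[is.finite(null)]
  n <- length(null)
  if (!n) stop("empty null distribution")
  vapply(observed, function(o) {
    if (!is.finite(o)) return(NA_real_)
    (sum(null >= o) + 1) / (n + 1)
  }, numeric(1))
}

#' Fold a one-tailed empirical p-value into a two-sided one
#'
#' `min(P, 1 - P)`: a statistic far into either tail of its null is
#' significant.
#'
#' @param p Empirical p-value(s).
#' @return Folded value(s).
#' @export
fold_two_sided <- function(p) pmin(p, 1 - p)
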
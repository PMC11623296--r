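#' Organotropism specificity analysis across candidate target tissues
#'
#' For a set of metastatic samples with known origin tissue, computes
#' normalized TD ratios treating every candidate tissue in turn as the
#' target, then asks — per candidate — whether the ratios under the true
#' target are significantly higher (paired one-sided Wilcoxon signed-rank
#' across samples, BH FDR over candidates). The specificity score is the
#' number of candidates beaten at `fdr < alpha`; a candidate whose
#' profile ties the true target exactly yields p = 1 and contributes 0.
#'
#' @param m Harmonized [expr_matrix()] with the metastatic samples.
#' @param met_samples Sample ids of the metastases (>= 3; the paired test
#'   uses the same samples across candidates).
#' @param ot_ref Origin-tissue reference profile.
#' @param candidate_tt_refs Named list of >= 2 candidate target-tissue
#'   profiles, including the true target.
#' @param true_tt Name of the true target tissue.
#' @param measure Distance measure.
#' @param alpha FDR threshold counted into the score (default 0.1).
#' @param pseudocount Log-transform pseudocount.
#' @return List of class `specificity_result`: `true_tt`, `score`,
#'   `ratios` (sample x candidate matrix of normalized TD ratios) and
#'   `table` (per candidate: median ratio, p, fdr, counted flag).
#' @export
specificity_analysis <- function(m, met_samples, ot_ref, candidate_tt_refs,
                                 true_tt, measure = "euclidean", alpha = 0.1,
                                 pseudocount = 1) {
  measure <- match.arg(measure, .measures)
  if (length(met_samples) < 3) {
    stop("need >= 3 metastatic samples for the paired specificity test")
  }
  if (length(candidate_tt_refs) < 2) stop("need >= 2 candidate target tissues")
  if (!true_tt %in% names(candidate_tt_refs)) {
    stop("true target tissue '", true_tt, "' absent from candidates")
  }
  missing_ids <- setdiff(met_samples, colnames(m))
  if (length(missing_ids)) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  }
  log_space <- expr_state(m) == "log_space"
  vals <- unclass(m)[, met_samples, drop = FALSE]
  ratios <- sapply(candidate_tt_refs, function(ref) {
    apply(vals, 2, normalized_td_ratio, ot_ref = ot_ref, tt_ref = ref,
          measure = measure, pseudocount = pseudocount, log_space = log_space)
  })
  others <- setdiff(names(candidate_tt_refs), true_tt)
  p <- vapply(others, function(cand) {
    d <- ratios[, true_tt] - ratios[, cand]
    d <- d[is.finite(d)]
    if (!length(d) || all(d == 0)) return(1)
    suppressMessages(wilcoxon_signed_rank(d, alternative = "greater")$p)
  }, numeric(1))
  fdr <- bh_fdr(p)
  tab <- data.frame(candidate_tt = others,
                    median_normalized_ratio = apply(
                      ratios[, others, drop = FALSE], 2,
                      function(x) stats::median(x[is.finite(x)])),
                    p = p, fdr = fdr, counted = fdr < alpha,
                    stringsAsFactors = FALSE)
  tab <- tab[order(tab$fdr, tab$candidate_tt), ]
  rownames(tab) <- NULL
  structure(list(true_tt = true_tt,
                 true_median = stats::median(ratios[, true_tt][is.finite(ratios[, true_tt])]),
                 score = sum(tab$counted), n_candidates = length(others),
                 ratios = ratios, table = tab),
            class = "specificity_result")
}

#' @export
print.specificity_result <- function(x, ...) {
  cat(sprintf("specificity: true TT '%s' beats %d of %d candidates (score = %d)\n",
              x$true_tt, x$score, x$n_candidates, x$score))
  invisible(x)
}

#' Spearman association between TD ratios and tumor purity
#'
#' Computed within one class (primary or metastatic) to decide whether a
#' dataset's ratios need purity residualization (the adjustment trigger
#' is p < 0.05). Constant purity makes the correlation undefined and is
#' reported as not adjustable with a warning.
#'
#' @param ratios Per-sample TD ratios.
#' @param purity Per-sample purity in \[0, 1\].
#' @return List: `rho`, `p`, `n`, `adjustable`.
#' @export
purity_association <- function(ratios, purity) {
  keep <- is.finite(ratios) & is.finite(purity)
  if (sum(keep) < 3) stop("need >= 3 samples with purity to test association")
  r <- ratios[keep]; u <- purity[keep]
  if (stats::sd(u) == 0) {
    warning("constant purity; association undefined, no adjustment possible")
    return(list(rho = NA_real_, p = NA_real_, n = sum(keep), adjustable = FALSE))
  }
  ct <- suppressWarnings(stats::cor.test(r, u, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep),
       adjustable = TRUE)
}

#' Replace TD ratios by their purity-regression residuals
#'
#' Ordinary least-squares residuals of `ratio ~ purity`; applied when the
#' Spearman association is significant (p < 0.05). Residuals have mean
#' zero, carry no linear purity component, and residualizing them again
#' returns the same vector.
#'
#' @param ratios Per-sample TD ratios (finite).
#' @param purity Per-sample purity (finite, same length).
#' @return Numeric residual vector, same length and order as `ratios`.
#' @export
purity_residualize <- function(ratios, purity) {
  if (length(ratios) != length(purity)) stop("length mismatch")
  if (length(ratios) < 3) stop("need >= 3 samples to residualize")
  if (any(!is.finite(ratios)) || any(!is.finite(purity))) {
    stop("residualization needs finite ratios and purity")
  }
  unname(stats::resid(stats::lm(ratios ~ purity)))
}
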
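#' Per-gene log2 fold change of geometric means, metastatic over primary
#'
#' For each gene, `log2` of the geometric mean over metastatic samples
#' divided by the geometric mean over primary samples, with the
#' pseudocount added before the mean so zero counts are defined
#' (unlogged linear-scale input is required).
#'
#' @param primary,metastatic Harmonized [expr_matrix()] objects on a
#'   linear scale.
#' @param pseudocount Added before the geometric mean (default 1).
#' @param from_log Set `TRUE` to accept log-space input and back-transform
#'   it (2^x) first.
#' @return Named per-gene numeric vector (positive = higher in
#'   metastases).
#' @export
geometric_log2_fold_change <- function(primary, metastatic, pseudocount = 1,
                                       from_log = FALSE) {
  if (!identical(rownames(primary), rownames(metastatic))) {
    stop("matrices must be harmonized to the same gene order")
  }
  grab <- function(m) {
    v <- unclass(m)[, , drop = FALSE]
    if (expr_state(m) == "log_space") {
      if (!from_log) {
        stop("log-space input: set from_log = TRUE to back-transform")
      }
      v <- 2^v
    }
    v
  }
  vp <- grab(primary); vm <- grab(metastatic)
  rowMeans(log2(vm + pseudocount)) - rowMeans(log2(vp + pseudocount))
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score. Hit
# increments are proportional to |score|^weight, miss decrements are
# uniform; the ES is the extremum of the running sum (positive wins ties).
# `ord_stats` must be sorted decreasing; `hit_pos` are positions of the
# set's genes in that order.
.gsea_es <- function(ord_stats, hit_pos, weight = 1) {
  N <- length(ord_stats)
  k <- length(hit_pos)
  if (k == 0) stop("empty gene set after pruning")
  if (k >= N) stop("gene set covers all ranked genes; miss distribution undefined")
  hit_pos <- sort(hit_pos)
  w <- abs(ord_stats[hit_pos])^weight
  sw <- sum(w)
  phit <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  pmiss <- (hit_pos - seq_len(k)) / (N - k)
  after <- phit - pmiss              # running sum just after each hit
  before <- c(0, phit[-k]) - pmiss   # and just before it
  hi <- max(after)
  lo <- min(before)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked gene-set enrichment with a random-gene-set null
#'
#' Classic weighted running-sum enrichment scores on a ranked gene list,
#' with an empirical null built from random same-size gene sets (gene
#' permutation). `NES = ES / mean(|null ES| of the same sign)`; the
#' empirical p uses `(r + 1)/(n + 1)` within the same-sign null, and BH
#' FDR is taken across sets. Positive NES means the set is concentrated
#' at the top of the ranking (metastatic-enriched when the ranking is a
#' metastatic-over-primary fold change).
#'
#' @param ranks Named numeric vector of per-gene scores (finite).
#' @param gene_sets Named list of gene sets; each is pruned to the ranked
#'   genes, and sets empty after pruning are dropped with a warning.
#' @param n_perm Null permutations per set size (default 10000).
#' @param seed Optional seed for the null draws.
#' @param weight Exponent on |score| for hit increments (default 1).
#' @return Data frame: `gene_set`, `size`, `es`, `nes`, `p`, `fdr`,
#'   `direction` (`"metastatic"` for nes > 0, `"primary"` for nes < 0).
#' @export
preranked_gsea <- function(ranks, gene_sets, n_perm = 10000, seed = NULL,
                           weight = 1) {
  if (any(!is.finite(ranks))) stop("ranks must be finite")
  if (is.null(names(ranks))) stop("ranks must be named by gene")
  ord <- order(ranks, decreasing = TRUE)
  ord_stats <- ranks[ord]
  pos_of <- stats::setNames(seq_along(ord), names(ranks)[ord])
  N <- length(ranks)
  pruned <- lapply(gene_sets, function(s) unique(s[s %in% names(ranks)]))
  empty <- lengths(pruned) == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " set(s) empty after pruning to ranked genes")
    pruned <- pruned[!empty]
  }
  if (!length(pruned)) stop("no gene sets left after pruning")
  es <- vapply(pruned, function(s) .gsea_es(ord_stats, pos_of[s], weight),
               numeric(1))
  sizes <- lengths(pruned)
  out <- .with_seed(seed, {
    null_cache <- list()
    null_for <- function(k) {
      key <- as.character(k)
      if (is.null(null_cache[[key]])) {
        null_cache[[key]] <<- vapply(seq_len(n_perm), function(i) {
          .gsea_es(ord_stats, sample.int(N, k), weight)
        }, numeric(1))
      }
      null_cache[[key]]
    }
    nes <- numeric(length(es)); p <- numeric(length(es))
    for (i in seq_along(es)) {
      null <- null_for(sizes[i])
      same <- if (es[i] >= 0) null[null >= 0] else null[null < 0]
      if (!length(same)) {
        # no same-sign permutation: most extreme achievable outcome
        nes[i] <- es[i] / mean(abs(null))
        p[i] <- 1 / (n_perm + 1)
      } else {
        nes[i] <- es[i] / mean(abs(same))
        p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
      }
    }
    list(nes = nes, p = p)
  })
  data.frame(gene_set = names(pruned), size = sizes, es = es,
             nes = out$nes, p = out$p, fdr = bh_fdr(out$p),
             direction = ifelse(out$nes > 0, "metastatic", "primary"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank-based single-sample gene-set activity scores
#'
#' A single-sample enrichment in the ssGSEA family: per sample, genes are
#' ranked by expression and the score is the normalized area between the
#' rank-weighted in-set ECDF (weights `rank^tau`) and the uniform out-set
#' ECDF. Being purely rank-based, the score is invariant to any strictly
#' monotone transform of a sample's values — the property the downstream
#' between-group rank tests rely on. This is this package's activity
#' score; it is not the GSVA kernel algorithm.
#'
#' @param m An [expr_matrix()] (>= 2 genes).
#' @param gene_sets Named list of gene sets.
#' @param tau Rank-weight exponent (default 0.25).
#' @param overlap_threshold Minimum fraction of each set present
#'   (default: any overlap; raise to filter sparse sets).
#' @return Data frame: `sample_id`, `gene_set`, `score`.
#' @export
single_sample_activity <- function(m, gene_sets, tau = 0.25,
                                   overlap_threshold = NULL) {
  if (nrow(m) < 2) stop("need >= 2 genes")
  genes <- rownames(m)
  pruned <- lapply(gene_sets, function(s) unique(s[s %in% genes]))
  if (!is.null(overlap_threshold)) {
    keep <- vapply(seq_along(gene_sets), function(i) {
      length(pruned[[i]]) / length(gene_sets[[i]]) >= overlap_threshold
    }, TRUE)
    pruned <- pruned[keep]
  }
  bad <- lengths(pruned) == 0 | lengths(pruned) >= length(genes)
  if (any(lengths(pruned) == 0)) stop("empty set intersection with matrix genes")
  pruned <- pruned[!bad]
  vals <- unclass(m)[, , drop = FALSE]
  rows <- list()
  for (j in seq_len(ncol(vals))) {
    rnk <- rank(vals[, j], ties.method = "average")
    ord <- order(vals[, j], decreasing = TRUE)
    in_ord_rank <- rnk[ord]
    for (p in names(pruned)) {
      hit <- genes[ord] %in% pruned[[p]]
      k <- sum(hit)
      w <- in_ord_rank^tau * hit
      phit <- cumsum(w) / sum(w)
      pmiss <- cumsum(!hit) / (length(genes) - k)
      score <- sum(phit - pmiss) / length(genes)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = colnames(vals)[j], gene_set = p, score = score,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare single-sample activity scores between two groups
#'
#' Wilcoxon rank-sum test per gene set (two-sided by default, matching
#' the activity-score convention), BH FDR across sets.
#'
#' @param scores Table from [single_sample_activity()].
#' @param groups Named character vector mapping sample id to group label
#'   (exactly two labels, >= 3 samples each).
#' @param alternative Test direction, for `first level vs second`.
#' @return Data frame per gene set: group medians, `statistic`, `p`,
#'   `fdr`.
#' @export
compare_group_activity <- function(scores, groups,
                                   alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  lv <- sort(unique(groups))
  if (length(lv) != 2) stop("need exactly two group labels")
  g <- groups[scores$sample_id]
  if (anyNA(g)) stop("samples in scores missing from groups: ",
                     paste(utils::head(unique(scores$sample_id[is.na(g)]), 5),
                           collapse = ", "))
  rows <- lapply(split(seq_len(nrow(scores)), scores$gene_set), function(ii) {
    a <- scores$score[ii][g[ii] == lv[1]]
    b <- scores$score[ii][g[ii] == lv[2]]
    if (length(a) < 3 || length(b) < 3) {
      stop("need >= 3 samples per group (", lv[1], ": ", length(a),
           ", ", lv[2], ": ", length(b), ")")
    }
    ht <- wilcoxon_rank_sum(a, b, alternative = alternative)
    data.frame(gene_set = scores$gene_set[ii[1]],
               median_1 = stats::median(a), median_2 = stats::median(b),
               statistic = ht$statistic, p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "median_1"] <- paste0("median_", lv[1])
  names(out)[names(out) == "median_2"] <- paste0("median_", lv[2])
  out$fdr <- bh_fdr(out$p)
  rownames(out) <- NULL
  out
}

#' Direction-bias control: enrichment of random gene sets
#'
#' Runs the pre-ranked enrichment on randomly drawn gene sets; on null
#' data no selective enrichment toward either group should appear — the
#' significant fraction stays near the FDR threshold's nominal level and
#' the direction split stays near 50/50.
#'
#' @param ranks Named per-gene score vector.
#' @param n_sets Number of random sets.
#' @param sizes Vector of sizes to sample from.
#' @param n_perm Null permutations inside the enrichment.
#' @param seed Seed.
#' @param fdr_threshold Significance threshold summarized (default 0.1).
#' @return List: `summary` (one-row data frame: `n_sets`,
#'   `frac_significant`, `n_positive`, `n_negative`, `frac_positive`) and
#'   `results` (the per-set table).
#' @export
random_set_enrichment_control <- function(ranks, n_sets = 500,
                                          sizes = c(25, 50, 100),
                                          n_perm = 500, seed = NULL,
                                          fdr_threshold = 0.1) {
  sets <- .with_seed(seed, {
    sz <- sizes[sample.int(length(sizes), n_sets, replace = TRUE)]
    stats::setNames(lapply(sz, function(s) sample(names(ranks), s)),
                    sprintf("RANDOM_%04d", seq_len(n_sets)))
  })
  res <- preranked_gsea(ranks, sets, n_perm = n_perm,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  summary <- data.frame(
    n_sets = nrow(res),
    frac_significant = mean(res$fdr < fdr_threshold),
    n_positive = sum(res$nes > 0),
    n_negative = sum(res$nes < 0),
    frac_positive = mean(res$nes > 0))
  list(summary = summary, results = res)
}
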
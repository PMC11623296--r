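#' Restrict a gene set to the available genes, subject to an overlap
#' threshold
#'
#' A pathway is only analyzed if a sufficient fraction of its genes is
#' present in the dataset: 0.9 is the bulk convention, 0.7 the
#' single-cell one (sparser data). The boundary is inclusive.
#'
#' @param genes_available Genes present in the harmonized dataset.
#' @param gene_set Character vector of pathway genes.
#' @param overlap_threshold Required fraction of the set present, in
#'   (0, 1\].
#' @return List: `accepted` (logical), `genes` (the intersection, in set
#'   order), `overlap` (achieved fraction).
#' @export
pathway_gene_subset <- function(genes_available, gene_set,
                                overlap_threshold = 0.9) {
  if (!length(gene_set)) stop("empty gene set")
  if (overlap_threshold <= 0 || overlap_threshold > 1) {
    stop("overlap_threshold must lie in (0, 1]")
  }
  genes <- gene_set[gene_set %in% genes_available]
  overlap <- length(genes) / length(gene_set)
  list(accepted = overlap >= overlap_threshold, genes = genes,
       overlap = overlap)
}

#' Draw reproducible random gene sets of a fixed size
#'
#' Uniform draws without replacement within each set, used to build the
#' empirical null for pathway-level statistics.
#'
#' @param genes_available Gene universe.
#' @param size Set size (each draw).
#' @param n_iter Number of draws.
#' @param seed Optional seed; the same seed reproduces the draws exactly.
#' @return List of `n_iter` character vectors.
#' @export
draw_random_gene_sets <- function(genes_available, size, n_iter, seed = NULL) {
  if (size > length(genes_available)) {
    stop("set size ", size, " exceeds ", length(genes_available), " available genes")
  }
  if (n_iter < 1) stop("n_iter must be >= 1")
  .with_seed(seed, replicate(n_iter, sample(genes_available, size),
                             simplify = FALSE))
}

# ---- group construction --------------------------------------------------

# Build per-(cancer_type, class, TT) computation contexts: log-scale
# matrices and log-scale reference vectors, plus the all-genes per-sample
# values and their median.
.build_value_groups <- function(m, ann, references,
                                value_kind = c("td_ratio", "pmt_score"),
                                min_group_size = 3, pseudocount = 1) {
  value_kind <- match.arg(value_kind)
  tum <- ann[ann$role %in% c("primary", "metastatic"), , drop = FALSE]
  if (any(lengths(tum$target_tissues) != 1)) {
    stop("each tumor row must have exactly one target tissue; ",
         "run expand_pseudo_samples() first")
  }
  tum$tt <- vapply(tum$target_tissues, `[[`, "", 1)
  src <- if ("source_sample_id" %in% colnames(tum)) tum$source_sample_id else tum$sample_id
  Lfull <- .log_values(m, pseudocount)
  lrefs <- lapply(references, .log_values, pseudocount = pseudocount)
  groups <- list()
  if (value_kind == "td_ratio") {
    keys <- split(seq_len(nrow(tum)),
                  interaction(tum$cancer_type, tum$role, tum$tt, drop = TRUE))
    for (rows in keys) {
      if (length(rows) < min_group_size) next
      g <- list(cancer_type = tum$cancer_type[rows[1]],
                class = tum$role[rows[1]], tt = tum$tt[rows[1]],
                n = length(rows),
                L = Lfull[, src[rows], drop = FALSE],
                lot = lrefs[[tum$origin_tissue[rows[1]]]],
                ltt = lrefs[[tum$tt[rows[1]]]])
      groups[[length(groups) + 1]] <- g
    }
  } else {
    met <- tum[tum$role == "metastatic", , drop = FALSE]
    pri <- tum[tum$role == "primary", , drop = FALSE]
    met_src <- src[tum$role == "metastatic"]
    pri_src <- src[tum$role == "primary"]
    partner <- match(met$patient_id, pri$patient_id)
    keep <- !is.na(met$patient_id) & !is.na(partner)
    met <- met[keep, , drop = FALSE]
    met_src <- met_src[keep]
    partner <- partner[keep]
    keys <- split(seq_len(nrow(met)),
                  interaction(met$cancer_type, met$tt, drop = TRUE))
    for (rows in keys) {
      if (length(rows) < min_group_size) next
      g <- list(cancer_type = met$cancer_type[rows[1]],
                class = "metastatic", tt = met$tt[rows[1]],
                n = length(rows),
                L = Lfull[, met_src[rows], drop = FALSE],
                Lpri = Lfull[, pri_src[partner[rows]], drop = FALSE],
                ltt = lrefs[[met$tt[rows[1]]]])
      groups[[length(groups) + 1]] <- g
    }
  }
  groups
}

# Median per-sample value of a group over gene rows idx, dropping
# degenerate samples. Euclidean has a vectorized path; other measures
# loop over samples.
.group_median_value <- function(g, idx, value_kind, measure = "euclidean") {
  if (value_kind == "td_ratio") {
    if (measure == "euclidean") {
      vals <- .group_td_ratios(g$L, g$lot, g$ltt, idx)$ratio
    } else {
      vals <- apply(g$L[idx, , drop = FALSE], 2, function(lx) {
        d_ot <- .log_distance(lx, g$lot[idx], measure)
        d_tt <- .log_distance(lx, g$ltt[idx], measure)
        if (!is.finite(d_ot) || !is.finite(d_tt)) return(NA_real_)
        .safe_ratio(d_ot, d_tt)$ratio
      })
    }
  } else {
    if (measure != "euclidean") stop("PMT scores are defined on the euclidean measure")
    vals <- .group_pmt_scores(g$L, g$Lpri, g$ltt, idx)$pmt_score
  }
  vals <- vals[is.finite(vals)]
  if (!length(vals)) return(NA_real_)
  stats::median(vals)
}

# Distance between two log-scale vectors for the non-euclidean measures.
.log_distance <- function(lx, lr, measure) {
  if (measure == "spearman") {
    if (stats::sd(rank(lx)) == 0 || stats::sd(rank(lr)) == 0) return(NA_real_)
    return(1 - stats::cor(lx, lr, method = "spearman"))
  }
  zx <- .zscore_vec(lx); zr <- .zscore_vec(lr)
  if (anyNA(zx) || anyNA(zr)) return(NA_real_)
  if (measure == "euclidean") return(sqrt(sum((zx - zr)^2)))
  1 - sum(zx * zr) / sqrt(sum(zx^2) * sum(zr^2))
}

#' Pathway-restricted group values and their delta against the all-genes
#' baseline
#'
#' For every (cancer type, class, target tissue) group with at least
#' `min_group_size` samples and every pathway passing the overlap filter,
#' computes the median per-sample TD ratio (or PMT score) restricted to
#' the pathway genes, the same median over all genes, and their ratio
#' (`delta`). `delta > 1` means the pathway sits closer to the target
#' tissue than the transcriptome-wide tendency of the same samples.
#'
#' @param m Harmonized [expr_matrix()] with the tumor samples.
#' @param ann Annotation data frame (one target tissue per tumor row).
#' @param references Named list of reference profiles per tissue.
#' @param gene_sets Named list of pathway gene sets.
#' @param value_kind `"td_ratio"` or `"pmt_score"` (PMT needs paired
#'   primaries).
#' @param measure Distance measure (PMT scores are euclidean only).
#' @param overlap_threshold Passed to [pathway_gene_subset()].
#' @param min_group_size Minimum samples per group (default 3).
#' @param pseudocount Log-transform pseudocount.
#' @return Data frame: `cancer_type`, `class`, `target_tissue`,
#'   `pathway`, `n_samples`, `n_genes`, `pathway_value`,
#'   `all_genes_value`, `delta`.
#' @export
pathway_value_table <- function(m, ann, references, gene_sets,
                                value_kind = c("td_ratio", "pmt_score"),
                                measure = "euclidean",
                                overlap_threshold = 0.9,
                                min_group_size = 3,
                                pseudocount = 1) {
  value_kind <- match.arg(value_kind)
  measure <- match.arg(measure, .measures)
  groups <- .build_value_groups(m, ann, references, value_kind,
                                min_group_size, pseudocount)
  empty <- data.frame(cancer_type = character(), class = character(),
                      target_tissue = character(), pathway = character(),
                      n_samples = integer(), n_genes = integer(),
                      pathway_value = numeric(), all_genes_value = numeric(),
                      delta = numeric(), stringsAsFactors = FALSE)
  if (!length(groups)) {
    warning("no group meets min_group_size = ", min_group_size)
    return(empty)
  }
  genes_available <- rownames(m)
  subsets <- lapply(gene_sets, pathway_gene_subset,
                    genes_available = genes_available,
                    overlap_threshold = overlap_threshold)
  accepted <- vapply(subsets, `[[`, TRUE, "accepted")
  rows <- list()
  for (g in groups) {
    all_val <- .group_median_value(g, seq_len(nrow(g$L)), value_kind, measure)
    for (p in names(gene_sets)[accepted]) {
      idx <- match(subsets[[p]]$genes, genes_available)
      pv <- .group_median_value(g, idx, value_kind, measure)
      rows[[length(rows) + 1]] <- data.frame(
        cancer_type = g$cancer_type, class = g$class, target_tissue = g$tt,
        pathway = p, n_samples = g$n, n_genes = length(idx),
        pathway_value = pv, all_genes_value = all_val,
        delta = pv / all_val, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Attach empirical p-values, two-sided folding and BH FDR to a pathway
#' score table
#'
#' For each row, `r` counts null deltas at least as large as the observed
#' delta; the empirical p is `(r + 1)/(n + 1)`, folded two-sided as
#' `min(P, 1 - P)` because a pathway can be significantly shifted toward
#' either tissue, then BH-adjusted across all rows of the table.
#'
#' @param observed Table from [pathway_value_table()].
#' @param null_deltas List of numeric null-delta vectors: either one per
#'   row of `observed`, or named by pathway (shared across groups is not
#'   allowed — provide per-row nulls when groups differ).
#' @param alpha Significance threshold on the FDR (reported flag).
#' @return `observed` with `empirical_p`, `adjusted_p`, `fdr`,
#'   `significant` columns.
#' @export
empirical_pvalues <- function(observed, null_deltas, alpha = 0.1) {
  n <- nrow(observed)
  if (!is.list(null_deltas)) stop("null_deltas must be a list of numeric vectors")
  if (length(null_deltas) != n && !is.null(names(null_deltas))) {
    null_deltas <- null_deltas[observed$pathway]
  }
  if (length(null_deltas) != n || any(vapply(null_deltas, is.null, TRUE))) {
    stop("need one null distribution per observed row")
  }
  observed$empirical_p <- vapply(seq_len(n), function(i) {
    empirical_pvalue(observed$delta[i], null_deltas[[i]])
  }, numeric(1))
  observed$adjusted_p <- fold_two_sided(observed$empirical_p)
  observed$fdr <- bh_fdr(observed$adjusted_p)
  observed$significant <- !is.na(observed$fdr) & observed$fdr < alpha
  observed
}

#' Full pathway-level analysis: values, deltas, empirical nulls, FDR
#'
#' Composes [pathway_value_table()] with a random-gene-set empirical
#' null. For every group, null deltas are computed for random sets
#' matched in size to each accepted pathway; the null is cached per
#' (group, size) — pathways of equal size share draws, which is exact
#' re-use of the same null distribution.
#'
#' @inheritParams pathway_value_table
#' @param n_iter Null iterations per pathway (default 10000).
#' @param seed Seed for the null draws (default 1206).
#' @param alpha FDR significance threshold (default 0.1).
#' @return Score table with `empirical_p`, `adjusted_p`, `fdr`,
#'   `significant`.
#' @export
pathway_analysis <- function(m, ann, references, gene_sets,
                             value_kind = c("td_ratio", "pmt_score"),
                             measure = "euclidean",
                             overlap_threshold = 0.9,
                             min_group_size = 3,
                             n_iter = 10000,
                             seed = 1206,
                             alpha = 0.1,
                             pseudocount = 1) {
  value_kind <- match.arg(value_kind)
  measure <- match.arg(measure, .measures)
  observed <- pathway_value_table(m, ann, references, gene_sets, value_kind,
                                  measure, overlap_threshold, min_group_size,
                                  pseudocount)
  if (!nrow(observed)) return(observed)
  if (n_iter < 1) stop("n_iter must be >= 1")
  groups <- .build_value_groups(m, ann, references, value_kind,
                                min_group_size, pseudocount)
  gkey <- vapply(groups, function(g) paste(g$cancer_type, g$class, g$tt, sep = "\r"), "")
  okey <- paste(observed$cancer_type, observed$class, observed$target_tissue, sep = "\r")
  genes_available <- rownames(m)
  nulls <- vector("list", nrow(observed))
  .with_seed(seed, {
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      rows <- which(okey == gkey[gi])
      if (!length(rows)) next
      all_val <- observed$all_genes_value[rows[1]]
      cache <- list()
      for (i in rows) {
        s <- as.character(observed$n_genes[i])
        if (is.null(cache[[s]])) {
          k <- observed$n_genes[i]
          cache[[s]] <- vapply(seq_len(n_iter), function(j) {
            idx <- sample.int(length(genes_available), k)
            .group_median_value(g, idx, value_kind, measure) / all_val
          }, numeric(1))
        }
        nulls[[i]] <- cache[[s]]
      }
    }
  })
  empirical_pvalues(observed, nulls, alpha = alpha)
}
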
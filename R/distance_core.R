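#' Log-transform and z-score standardize an expression vector
#'
#' Linear-scale vectors are log2-transformed after adding `pseudocount`;
#' log-space vectors are used as-is. The result has mean 0 and standard
#' deviation 1 (n - 1 denominator). A vector that is constant after the
#' log transform has no direction in expression space and raises a
#' zero-variance error.
#'
#' @param x Numeric vector (length >= 2, finite).
#' @param pseudocount Added before log2 on linear-scale data; default 1.
#' @param log_space If `TRUE`, `x` is already log-transformed and the
#'   pseudocount is skipped.
#' @return Standardized numeric vector.
#' @export
standardize_vector <- function(x, pseudocount = 1, log_space = FALSE) {
  if (length(x) < 2) stop("need >= 2 values to standardize")
  if (any(!is.finite(x))) stop("non-finite values in expression vector")
  lx <- if (log_space) x else log2(x + pseudocount)
  s <- stats::sd(lx)
  if (s == 0) stop("zero variance after log transform; cannot z-score")
  (lx - mean(lx)) / s
}

.measures <- c("euclidean", "spearman", "cosine")

#' Transcriptomic distance between a sample and a reference profile
#'
#' The Euclidean measure is the L2 distance between the z-scored log2
#' vectors. The Spearman measure is `1 - rho` on the (pre-standardization)
#' log values, and the cosine measure is `1 - cosine similarity` of the
#' standardized vectors; both are this package's conventions for
#' correlation-based distances. All three are 0 when `x` equals the
#' reference.
#'
#' @param x Expression vector, same gene order as `ref`.
#' @param ref Reference profile (or plain numeric vector), same gene order.
#' @param measure One of `"euclidean"`, `"spearman"`, `"cosine"`.
#' @param pseudocount Passed to [standardize_vector()].
#' @param log_space Whether inputs are already log-transformed.
#' @return Non-negative scalar distance.
#' @export
transcriptomic_distance <- function(x, ref, measure = .measures,
                                    pseudocount = 1, log_space = FALSE) {
  measure <- match.arg(measure)
  if (length(x) != length(ref)) {
    stop("length mismatch: sample has ", length(x), " genes, reference ", length(ref))
  }
  if (measure == "spearman") {
    lx <- if (log_space) x else log2(x + pseudocount)
    lr <- if (log_space) as.numeric(ref) else log2(as.numeric(ref) + pseudocount)
    if (stats::sd(rank(lx)) == 0 || stats::sd(rank(lr)) == 0) {
      stop("zero variance after log transform; cannot z-score")
    }
    return(1 - stats::cor(lx, lr, method = "spearman"))
  }
  zx <- standardize_vector(x, pseudocount, log_space)
  zr <- standardize_vector(as.numeric(ref), pseudocount, log_space)
  if (measure == "euclidean") {
    sqrt(sum((zx - zr)^2))
  } else {
    1 - sum(zx * zr) / sqrt(sum(zx^2) * sum(zr^2))
  }
}

# Ratio with the degenerate-denominator convention used throughout:
# d_tt > 0 -> d_ot / d_tt; both zero -> 1 (the sample sits on both
# references); d_tt = 0 alone -> +Inf, flagged so aggregation can drop it.
.safe_ratio <- function(d_num, d_den) {
  if (d_den > 0) {
    list(ratio = d_num / d_den, degenerate = FALSE)
  } else if (d_num == 0) {
    list(ratio = 1, degenerate = FALSE)
  } else {
    list(ratio = Inf, degenerate = TRUE)
  }
}

#' TD ratio of a tumor sample: distance to origin over distance to target
#'
#' Ratios above 1 mean the sample is transcriptionally closer to the
#' target tissue than to its tissue of origin; below 1, closer to the
#' origin. A zero distance to the target tissue yields a flagged `Inf`
#' sentinel (1 if both distances are zero) rather than an error, so
#' cohort-level aggregation can drop degenerate samples with a count.
#'
#' @param x Tumor expression vector.
#' @param ot_ref Origin-tissue reference profile.
#' @param tt_ref Target-tissue reference profile.
#' @inheritParams transcriptomic_distance
#' @param sample_id Optional id recorded in the result.
#' @return One-row data frame: `sample_id`, `measure`, `td_ot`, `td_tt`,
#'   `ratio`, `degenerate`.
#' @export
td_ratio <- function(x, ot_ref, tt_ref, measure = .measures,
                     pseudocount = 1, log_space = FALSE,
                     sample_id = NA_character_) {
  measure <- match.arg(measure)
  d_ot <- transcriptomic_distance(x, ot_ref, measure, pseudocount, log_space)
  d_tt <- transcriptomic_distance(x, tt_ref, measure, pseudocount, log_space)
  r <- .safe_ratio(d_ot, d_tt)
  data.frame(sample_id = sample_id, measure = measure,
             td_ot = d_ot, td_tt = d_tt,
             ratio = r$ratio, degenerate = r$degenerate,
             stringsAsFactors = FALSE)
}

#' Normalized TD ratio for specificity comparisons across candidate targets
#'
#' Replaces the sample-to-origin numerator of the TD ratio with the
#' origin-to-target reference distance, which is constant across samples
#' for a fixed (OT, TT) pair. This removes the sample term from the
#' numerator so candidate target tissues with very different baseline
#' similarity to the origin can be compared fairly.
#'
#' @inheritParams td_ratio
#' @return Non-negative scalar; flagged `Inf` when the sample coincides
#'   with the target reference.
#' @export
normalized_td_ratio <- function(x, ot_ref, tt_ref, measure = .measures,
                                pseudocount = 1, log_space = FALSE) {
  measure <- match.arg(measure)
  d_refs <- transcriptomic_distance(as.numeric(ot_ref), tt_ref, measure,
                                    pseudocount, log_space)
  d_tt <- transcriptomic_distance(x, tt_ref, measure, pseudocount, log_space)
  .safe_ratio(d_refs, d_tt)$ratio
}

#' PMT score: distance of a metastasis to its paired primary over its
#' distance to the target tissue
#'
#' Scores above 1 mean the metastasis is closer in expression to the
#' target tissue than to its own paired primary tumor. Euclidean distance
#' on standardized vectors, per convention.
#'
#' @param met Metastatic sample expression vector.
#' @param primary Paired primary sample expression vector.
#' @param tt_ref Target-tissue reference profile.
#' @inheritParams transcriptomic_distance
#' @param met_sample_id,primary_sample_id,tt Optional ids recorded in the
#'   result.
#' @return One-row data frame: ids, `tt`, `pmt_score`, `degenerate`.
#' @export
pmt_score <- function(met, primary, tt_ref, measure = "euclidean",
                      pseudocount = 1, log_space = FALSE,
                      met_sample_id = NA_character_,
                      primary_sample_id = NA_character_,
                      tt = NA_character_) {
  measure <- match.arg(measure, .measures)
  d_pri <- transcriptomic_distance(met, primary, measure, pseudocount, log_space)
  d_tt <- transcriptomic_distance(met, tt_ref, measure, pseudocount, log_space)
  r <- .safe_ratio(d_pri, d_tt)
  data.frame(met_sample_id = met_sample_id,
             primary_sample_id = primary_sample_id,
             tt = tt, pmt_score = r$ratio, degenerate = r$degenerate,
             stringsAsFactors = FALSE)
}

# ---- vectorized internals shared by cohort/pathway/null loops ------------

# Column-standardize a log-scale gene x sample matrix; columns with zero
# sd come back as NA and are treated as degenerate downstream.
.zscore_cols <- function(L) {
  Z <- scale(L)
  attr(Z, "scaled:center") <- NULL
  attr(Z, "scaled:scale") <- NULL
  Z
}

.zscore_vec <- function(lx) {
  s <- stats::sd(lx)
  if (is.na(s) || s == 0) return(rep(NA_real_, length(lx)))
  (lx - mean(lx)) / s
}

# Per-sample euclidean TD ratios of the columns of log-matrix L against
# log reference vectors lot/ltt, restricted to gene rows `idx`.
# Returns list(td_ot, td_tt, ratio, degenerate) vectors.
.group_td_ratios <- function(L, lot, ltt, idx = seq_len(nrow(L))) {
  Z <- .zscore_cols(L[idx, , drop = FALSE])
  zo <- .zscore_vec(lot[idx])
  zt <- .zscore_vec(ltt[idx])
  d_ot <- sqrt(colSums((Z - zo)^2))
  d_tt <- sqrt(colSums((Z - zt)^2))
  n <- length(d_ot)
  ratio <- numeric(n)
  degenerate <- logical(n)
  bad <- !is.finite(d_ot) | !is.finite(d_tt)
  for (i in seq_len(n)) {
    if (bad[i]) {
      ratio[i] <- NA_real_; degenerate[i] <- TRUE
    } else {
      r <- .safe_ratio(d_ot[i], d_tt[i])
      ratio[i] <- r$ratio; degenerate[i] <- r$degenerate
    }
  }
  list(td_ot = d_ot, td_tt = d_tt, ratio = ratio, degenerate = degenerate)
}

# Per-met-sample euclidean PMT scores: columns of Lmet vs paired columns
# of Lpri (same column count/order) and log reference ltt, on rows idx.
.group_pmt_scores <- function(Lmet, Lpri, ltt, idx = seq_len(nrow(Lmet))) {
  Zm <- .zscore_cols(Lmet[idx, , drop = FALSE])
  Zp <- .zscore_cols(Lpri[idx, , drop = FALSE])
  zt <- .zscore_vec(ltt[idx])
  d_pri <- sqrt(colSums((Zm - Zp)^2))
  d_tt <- sqrt(colSums((Zm - zt)^2))
  n <- length(d_pri)
  score <- numeric(n)
  degenerate <- logical(n)
  bad <- !is.finite(d_pri) | !is.finite(d_tt)
  for (i in seq_len(n)) {
    if (bad[i]) {
      score[i] <- NA_real_; degenerate[i] <- TRUE
    } else {
      r <- .safe_ratio(d_pri[i], d_tt[i])
      score[i] <- r$ratio; degenerate[i] <- r$degenerate
    }
  }
  list(pmt_score = score, degenerate = degenerate)
}

# Log2-transform an expr_matrix (or plain matrix/vector) respecting state.
.log_values <- function(m, pseudocount = 1) {
  v <- if (inherits(m, "expr_matrix") || inherits(m, "reference_profile")) {
    st <- attr(m, "state")
    if (!is.null(st) && st == "log_space") return(unclass(m))
    unclass(m)
  } else {
    m
  }
  log2(v + pseudocount)
}

#' Per-sample TD ratios for a whole cohort
#'
#' Computes the TD ratio of every tumor sample in the annotation against
#' its origin- and target-tissue reference profiles. Samples with more
#' than one target tissue should be expanded with
#' [expand_pseudo_samples()] first; each annotated row must have exactly
#' one target tissue.
#'
#' @param m Harmonized [expr_matrix()] containing the tumor samples.
#' @param ann Annotation data frame (tumor rows are used).
#' @param references Named list of [build_reference_profile()] vectors,
#'   one per tissue, on the same gene order as `m`.
#' @inheritParams transcriptomic_distance
#' @return Data frame: `sample_id`, `patient_id`, `cancer_type`, `role`,
#'   `origin_tissue`, `target_tissue`, `measure`, `td_ot`, `td_tt`,
#'   `ratio`, `degenerate`.
#' @export
cohort_td_ratios <- function(m, ann, references, measure = .measures,
                             pseudocount = 1) {
  measure <- match.arg(measure)
  tum <- ann[ann$role %in% c("primary", "metastatic"), , drop = FALSE]
  if (!nrow(tum)) stop("no tumor samples in annotation")
  n_tt <- lengths(tum$target_tissues)
  if (any(n_tt != 1)) {
    stop("each tumor row must have exactly one target tissue; ",
         "run expand_pseudo_samples() first")
  }
  src <- if ("source_sample_id" %in% colnames(tum)) tum$source_sample_id else tum$sample_id
  missing_ids <- setdiff(src, colnames(m))
  if (length(missing_ids)) {
    stop("annotated sample(s) absent from matrix: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  log_space <- expr_state(m) == "log_space"
  rows <- lapply(seq_len(nrow(tum)), function(i) {
    ot <- tum$origin_tissue[i]
    tt <- tum$target_tissues[[i]][1]
    for (tis in c(ot, tt)) {
      if (!tis %in% names(references)) stop("no reference profile for tissue '", tis, "'")
    }
    res <- td_ratio(unclass(m)[, src[i]], references[[ot]], references[[tt]],
                    measure = measure, pseudocount = pseudocount,
                    log_space = log_space, sample_id = tum$sample_id[i])
    cbind(data.frame(patient_id = tum$patient_id[i],
                     cancer_type = tum$cancer_type[i],
                     role = tum$role[i],
                     origin_tissue = ot, target_tissue = tt,
                     stringsAsFactors = FALSE),
          res)
  })
  out <- do.call(rbind, rows)
  out[, c("sample_id", "patient_id", "cancer_type", "role", "origin_tissue",
          "target_tissue", "measure", "td_ot", "td_tt", "ratio", "degenerate")]
}
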
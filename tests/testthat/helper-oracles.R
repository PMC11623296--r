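# Independent oracles used by the tests. These deliberately re-derive the
# quantities from first principles (enumeration, direct formulas) and never
# call the package code paths they check.

# TMM scaling factors implemented directly from the published procedure:
# reference = sample whose 75th percentile of library-scaled counts is
# closest to the mean; 30% two-sided trim on M, 5% on A (rank-based);
# precision-weighted mean of trimmed M values; factors rescaled to
# geometric mean 1.
oracle_tmm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  lib <- colSums(counts)
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  refi <- which.min(abs(uq - mean(uq)))
  f <- sapply(seq_len(ncol(counts)), function(i) {
    keep <- counts[, i] > 0 & counts[, refi] > 0
    o <- counts[keep, i] / lib[i]
    r <- counts[keep, refi] / lib[refi]
    M <- log2(o / r)
    A <- (log2(o) + log2(r)) / 2
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    keep2 <- rank(M) >= floor(n * trim_m) + 1 & rank(M) <= n - floor(n * trim_m) &
      rank(A) >= floor(n * trim_a) + 1 & rank(A) <= n - floor(n * trim_a)
    w <- (1 - o) / counts[keep, i] + (1 - r) / counts[keep, refi]
    2^(sum(M[keep2] / w[keep2]) / sum(1 / w[keep2]))
  })
  f / exp(mean(log(f)))
}

# Exact one-sided signed-rank p by enumerating all 2^n sign assignments
# of the rank vector (tie-free differences assumed).
oracle_signed_rank_p <- function(d, alternative = "greater") {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 16, !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  if (alternative == "greater") mean(v_null >= v_obs) else mean(v_null <= v_obs)
}

# Exact one-sided rank-sum p by enumerating all choose(m+n, m) group
# assignments (tie-free pooled values assumed).
oracle_rank_sum_p <- function(x, y, alternative = "greater") {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled), length(pooled) <= 12)
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combs <- combn(length(pooled), m)
  w_null <- apply(combs, 2, function(ii) sum(r[ii]) - m * (m + 1) / 2)
  if (alternative == "greater") mean(w_null >= w_obs) else mean(w_null <= w_obs)
}

# BH step-up adjustment written out directly from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Brute-force weighted running-sum enrichment score: walk every position
# of the ranking and track the full running sum.
oracle_gsea_es <- function(ranks, set, weight = 1) {
  ord <- order(ranks, decreasing = TRUE)
  genes <- names(ranks)[ord]
  s <- abs(ranks[ord])^weight
  hit <- genes %in% set
  n_miss <- sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) s[i] / sum(s[hit]) else -1 / n_miss
    if (abs(run) > abs(best) ||
        (abs(run) == abs(best) && run > best)) best <- run
  }
  unname(best)
}

# Numeric payload of an expr_matrix without its class/state tags, for
# comparisons against plain matrices.
mat_values <- function(m) {
  v <- unclass(m)
  attributes(v) <- attributes(v)[c("dim", "dimnames")]
  v
}

# Brute-force rank-ECDF single-sample activity score.
oracle_ss_activity <- function(values, set, tau = 0.25) {
  genes <- names(values)
  rnk <- rank(values, ties.method = "average")
  ord <- order(values, decreasing = TRUE)
  hit <- genes[ord] %in% set
  w <- rnk[ord]^tau
  phit <- cumsum(ifelse(hit, w, 0)) / sum(w[hit])
  pmiss <- cumsum(!hit) / sum(!hit)
  sum(phit - pmiss) / length(genes)
}

# Small deterministic expression fixture written through the package's
# own writer is avoided here on purpose: tests that need raw TSVs write
# them with base R so reader bugs cannot cancel writer bugs.
write_raw_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# Convenience: simulated two-tissue setup shared by several test files.
make_small_world <- function(seed = 7, n_genes = 400, n_normals = 10,
                             n_patients = 10, ...) {
  cfg <- simulation_config(n_genes = n_genes, tissues = c("colon", "liver"),
                           n_normals = n_normals, n_patients = n_patients,
                           seed = seed, ...)
  ref <- generate_reference_cohort(cfg)
  tum <- generate_tumor_cohort(cfg, ref, "colon", "liver")
  refs <- lapply(setNames(cfg$tissues, cfg$tissues), function(t) {
    build_reference_profile(
      ref$matrix, ref$annotation$sample_id[ref$annotation$origin_tissue == t],
      tissue = t)
  })
  list(cfg = cfg, ref = ref, tumor = tum, refs = refs)
}
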
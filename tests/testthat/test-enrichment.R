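make_expr <- function(vals, state = "cpm") {
  expr_matrix(vals, state = state)
}

test_that("geometric-mean log2 fold changes follow the pseudocount
           convention", {
  g <- paste0("g", 1:3)
  pri <- make_expr(matrix(c(4, 8, 0, 4, 8, 0), ncol = 2,
                          dimnames = list(g, c("p1", "p2"))))
  met4 <- make_expr(matrix(c(16, 32, 3, 16, 32, 3), ncol = 2,
                           dimnames = list(g, c("m1", "m2"))))
  fc <- geometric_log2_fold_change(pri, met4, pseudocount = 0)
  expect_equal(unname(fc[1:2]), c(2, 2))
  fc1 <- geometric_log2_fold_change(pri, met4, pseudocount = 1)
  expect_equal(unname(fc1[3]), log2(4 / 1))
  expect_equal(unname(geometric_log2_fold_change(pri, pri)), rep(0, 3))

  logm <- make_expr(matrix(1:6, ncol = 2, dimnames = list(g, c("a", "b"))),
                    state = "log_space")
  expect_error(geometric_log2_fold_change(logm, logm), "from_log")
})

test_that("enrichment scores match the brute-force running-sum oracle", {
  set.seed(50)
  ranks <- sort(rnorm(10), decreasing = TRUE)
  names(ranks) <- paste0("g", 1:10)
  top3 <- names(ranks)[1:3]
  bottom2 <- names(ranks)[9:10]
  res <- preranked_gsea(ranks, list(TOP = top3, BOTTOM = bottom2),
                        n_perm = 200, seed = 51)
  expect_equal(res$es[res$gene_set == "TOP"], oracle_gsea_es(ranks, top3),
               tolerance = 1e-12)
  expect_gt(res$es[res$gene_set == "TOP"], 0)
  expect_equal(res$es[res$gene_set == "BOTTOM"],
               oracle_gsea_es(ranks, bottom2), tolerance = 1e-12)
  expect_lt(res$es[res$gene_set == "BOTTOM"], 0)
  expect_identical(res$direction, c("metastatic", "primary"))

  # larger random fixtures against the oracle
  set.seed(52)
  ranks2 <- rnorm(60)
  names(ranks2) <- paste0("h", 1:60)
  for (i in 1:5) {
    set <- sample(names(ranks2), sample(5:20, 1))
    res2 <- preranked_gsea(ranks2, list(S = set), n_perm = 50, seed = i)
    expect_equal(res2$es, oracle_gsea_es(ranks2, set), tolerance = 1e-12)
  }
})

test_that("ES of a set and its complement have opposite signs and the
           minimal p respects the permutation bound", {
  set.seed(53)
  ranks <- rnorm(40)
  names(ranks) <- paste0("g", 1:40)
  set <- sample(names(ranks), 12)
  comp <- setdiff(names(ranks), set)
  res <- preranked_gsea(ranks, list(S = set, C = comp), n_perm = 99, seed = 54)
  expect_lt(prod(sign(res$es)), 0)
  expect_true(all(res$p >= 1 / 100))
  expect_error(preranked_gsea(ranks, list(ALL = names(ranks)), n_perm = 10),
               "covers all")
})

test_that("fgsea agrees with the package ES on a shared fixture", {
  skip_if_not_installed("fgsea")
  set.seed(55)
  ranks <- rnorm(100)
  names(ranks) <- paste0("g", 1:100)
  sets <- list(A = sample(names(ranks), 15), B = sample(names(ranks), 30))
  ours <- preranked_gsea(ranks, sets, n_perm = 100, seed = 56)
  theirs <- suppressWarnings(
    fgsea::fgsea(sets, ranks, minSize = 1, maxSize = 1000, eps = 0,
                 gseaParam = 1))
  expect_equal(ours$es[match(theirs$pathway, ours$gene_set)], theirs$ES,
               tolerance = 1e-6)
})

test_that("single-sample activity is rank-based and matches the ECDF
           oracle", {
  set.seed(57)
  n <- 20
  g <- sprintf("g%02d", 1:n)
  a <- setNames(seq(10, 1000, length.out = n), g)
  vals <- cbind(A = a, B = rev(a))
  rownames(vals) <- g
  m <- make_expr(vals)
  set_top <- g[order(a, decreasing = TRUE)][1:5]  # top genes of sample A
  act <- single_sample_activity(m, list(S = set_top))
  sA <- act$score[act$sample_id == "A"]
  sB <- act$score[act$sample_id == "B"]
  expect_gt(sA, sB)
  expect_equal(sA, oracle_ss_activity(vals[, "A"], set_top), tolerance = 1e-12)
  expect_equal(sB, oracle_ss_activity(vals[, "B"], set_top), tolerance = 1e-12)

  # strictly monotone transform of one sample leaves its score unchanged
  vals2 <- vals
  vals2[, "A"] <- exp(vals2[, "A"] / 200)
  act2 <- single_sample_activity(make_expr(vals2), list(S = set_top))
  expect_equal(act2$score[act2$sample_id == "A"], sA, tolerance = 1e-12)
  expect_error(single_sample_activity(m, list(S = "absent_gene")),
               "empty set intersection")
})

test_that("group comparison of activity scores flags a planted shift and
           rejects tiny groups", {
  set.seed(58)
  n_genes <- 120
  g <- sprintf("g%03d", 1:n_genes)
  base <- matrix(2^rnorm(n_genes * 40, 5, 1), nrow = n_genes,
                 dimnames = list(g, c(paste0("p", 1:20), paste0("m", 1:20))))
  planted <- g[1:15]
  sets <- list(PLANTED = planted, OTHER = g[50:70])
  groups <- setNames(rep(c("primary", "metastatic"), each = 20), colnames(base))

  # on the unplanted null matrix neither set separates the groups
  act0 <- single_sample_activity(make_expr(base), sets)
  cmp0 <- compare_group_activity(act0, groups)
  expect_true(all(cmp0$p > 0.05))

  shifted <- base
  shifted[planted, 21:40] <- shifted[planted, 21:40] * 8  # up in the "m" group
  act <- single_sample_activity(make_expr(shifted), sets)
  cmp <- compare_group_activity(act, groups)
  expect_lt(cmp$fdr[cmp$gene_set == "PLANTED"], 0.1)

  small <- groups
  small[1:18] <- "metastatic"  # leaves 2 primaries
  expect_error(compare_group_activity(act, small), ">= 3 samples per group")
})

test_that("random gene sets show no selective enrichment on null
           rankings", {
  set.seed(59)
  ranks <- rnorm(300)
  names(ranks) <- paste0("g", 1:300)
  ctrl <- random_set_enrichment_control(ranks, n_sets = 120,
                                        sizes = c(20, 40), n_perm = 200,
                                        seed = 60)
  expect_lte(ctrl$summary$frac_significant, 0.1)
  p0 <- 0.5
  expect_lt(abs(ctrl$summary$frac_positive - p0),
            3 * sqrt(p0 * (1 - p0) / ctrl$summary$n_sets))
  # reproducibility and the single-set edge case
  ctrl2 <- random_set_enrichment_control(ranks, n_sets = 120,
                                         sizes = c(20, 40), n_perm = 200,
                                         seed = 60)
  expect_equal(ctrl$results, ctrl2$results)
  one <- random_set_enrichment_control(ranks, n_sets = 1, sizes = 10,
                                       n_perm = 50, seed = 61)
  expect_equal(one$summary$n_sets, 1)
})
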
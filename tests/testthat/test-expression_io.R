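test_that("expression TSVs round-trip through read/write", {
  path <- write_raw_tsv(c("gene\ts1\ts2", "A\t1\t4", "B\t2\t5", "C\t3.5\t6"))
  m <- read_expression_matrix(path, state = "counts")
  expect_identical(rownames(m), c("A", "B", "C"))
  expect_identical(colnames(m), c("s1", "s2"))
  expect_equal(mat_values(m)[, "s2"], c(A = 4, B = 5, C = 6))
  expect_identical(expr_state(m), "counts")

  out <- tempfile(fileext = ".tsv")
  write_expression_matrix(m, out)
  m2 <- read_expression_matrix(out, state = "counts")
  expect_equal(mat_values(m2), mat_values(m), tolerance = 1e-12)
  expect_true(file.exists(paste0(out, ".yml")))
})

test_that("duplicate gene rows collapse by mean with a warning", {
  path <- write_raw_tsv(c("gene\ts1", "A\t2", "B\t1", "A\t4"))
  expect_warning(m <- read_expression_matrix(path, state = "counts"),
                 "duplicated gene")
  expect_equal(mat_values(m)["A", "s1"], 3)
  expect_identical(rownames(m), c("A", "B"))
})

test_that("non-numeric cells and duplicate sample ids are hard errors", {
  bad_cell <- write_raw_tsv(c("gene\ts1\ts2", "A\t1\tNA", "B\t2\t3"))
  expect_error(read_expression_matrix(bad_cell, state = "counts"),
               "gene 'A', sample 's2'")
  dup_sample <- write_raw_tsv(c("gene\ts1\ts1", "A\t1\t2"))
  expect_error(read_expression_matrix(dup_sample, state = "counts"),
               "duplicate sample ids")
  expect_error(read_expression_matrix(tempfile(), state = "counts"),
               "cannot read")
})

test_that("sample annotations parse, normalize roles, and validate purity", {
  path <- write_raw_tsv(c(
    "sample_id\tpatient_id\trole\tcancer_type\torigin_tissue\ttarget_tissues\tpurity",
    "m1\tpatientA\tmetastatic\tBRCA\tbreast\tliver;brain\t0.6",
    "p1\tpatientA\tPrimary\tBRCA\tbreast\tliver\t0.8",
    "n1\t\tNORMAL\t\tbreast\t\t"))
  ann <- read_sample_annotation(path)
  expect_identical(ann$target_tissues[[1]], c("liver", "brain"))
  expect_identical(ann$role, c("metastatic", "primary", "normal"))
  expect_equal(ann$purity[1], 0.6)

  bad <- write_raw_tsv(c("sample_id\trole\tpurity", "m1\tmetastatic\t1.4"))
  expect_error(read_sample_annotation(bad), "purity outside")
  bad_role <- write_raw_tsv(c("sample_id\trole", "m1\trelapse"))
  expect_error(read_sample_annotation(bad_role), "role values outside")
  no_role <- write_raw_tsv(c("sample_id\tpurity", "m1\t0.5"))
  expect_error(read_sample_annotation(no_role), "required column 'role'")
})

test_that("GMT parsing de-duplicates genes and rejects malformed files", {
  path <- write_raw_tsv(c("SET1\tdesc\tA\tB\tA", "SET2\tdesc\tC"))
  sets <- read_gene_sets_gmt(path)
  expect_identical(sets$SET1, c("A", "B"))
  expect_identical(sets$SET2, "C")

  expect_warning(empty <- read_gene_sets_gmt(write_raw_tsv(character())),
                 "empty GMT")
  expect_length(empty, 0)
  expect_error(read_gene_sets_gmt(write_raw_tsv(c("SET1\tdesc\tA", "SET1\tdesc\tB"))),
               "duplicate gene set names")
  expect_error(read_gene_sets_gmt(write_raw_tsv("SET1\tdesc")),
               "fewer than 3 fields")
})

test_that("CPM leaves a million-count sample unchanged and UQ uses the
           type-7 quantile", {
  counts <- matrix(c(2, 4, 6, 8), ncol = 1, dimnames = list(letters[1:4], "s1"))
  counts1e6 <- counts / sum(counts) * 1e6
  m <- expr_matrix(counts1e6, state = "counts")
  expect_equal(mat_values(normalize_counts(m, "cpm")), mat_values(m))

  uq <- normalize_counts(expr_matrix(counts, state = "counts"), "uq")
  expect_equal(mat_values(uq)[, 1], c(2, 4, 6, 8) / 6.5, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(expr_state(uq), "uq")

  zero <- expr_matrix(matrix(0, 2, 1, dimnames = list(c("a", "b"), "s1")),
                      state = "counts")
  expect_error(normalize_counts(zero, "cpm"), "zero library size")
})

test_that("TMM factors are 1 for identical samples and match the direct
           published-procedure oracle otherwise", {
  same <- matrix(rep(c(5, 10, 20, 40, 80), 3), ncol = 3,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  m <- expr_matrix(same, state = "counts")
  expect_equal(mat_values(normalize_counts(m, "tmm_cpm")),
               mat_values(normalize_counts(m, "cpm")), tolerance = 1e-10)

  set.seed(42)
  counts <- matrix(rnbinom(300 * 4, mu = 80, size = 5) + 1, nrow = 300,
                   dimnames = list(paste0("g", 1:300), paste0("s", 1:4)))
  mm <- expr_matrix(counts, state = "counts")
  got <- mat_values(normalize_counts(mm, "tmm_cpm"))
  f <- oracle_tmm_factors(counts)
  lib <- colSums(counts)
  want <- sweep(counts, 2, lib * f / 1e6, "/")
  expect_equal(got, want, tolerance = 1e-8)
})

test_that("cpm and uq normalization preserve within-sample gene ranks", {
  set.seed(3)
  counts <- matrix(rpois(200, 40), nrow = 50,
                   dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  m <- expr_matrix(counts, state = "counts")
  for (method in c("cpm", "uq")) {
    norm <- mat_values(normalize_counts(m, method))
    for (j in 1:4) expect_identical(rank(norm[, j]), rank(counts[, j]))
  }
})

test_that("gene harmonization intersects, sorts, and is idempotent", {
  m1 <- expr_matrix(matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2"))),
                    state = "cpm")
  m2 <- expr_matrix(matrix(1:6, 3, 2, dimnames = list(c("D", "C", "B"), c("t1", "t2"))),
                    state = "cpm")
  hm <- harmonize_genes(list(m1, m2))
  expect_identical(rownames(hm[[1]]), c("B", "C"))
  expect_identical(rownames(hm[[2]]), c("B", "C"))
  expect_identical(expr_state(hm[[1]]), "cpm")

  again <- harmonize_genes(hm)
  expect_equal(lapply(again, unclass), lapply(hm, unclass))

  m3 <- expr_matrix(matrix(1:2, 1, 2, dimnames = list("Z", c("u1", "u2"))),
                    state = "cpm")
  expect_error(harmonize_genes(list(m1, m3)), "empty gene intersection")
})

test_that("reference profiles take per-gene medians or means", {
  vals <- matrix(c(1, 2, 9, 5, 5, 5), nrow = 2, byrow = TRUE,
                 dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  m <- expr_matrix(vals, state = "cpm")
  expect_equal(build_reference_profile(m, c("s1", "s2", "s3"), "median")[["gA"]], 2)
  expect_equal(build_reference_profile(m, c("s1", "s2", "s3"), "mean")[["gA"]], 4)
  one <- build_reference_profile(m, "s2", "median")
  expect_equal(as.numeric(one), vals[, "s2"], ignore_attr = TRUE)
  expect_error(build_reference_profile(m, character()), "empty sample list")
  expect_error(build_reference_profile(m, "nope"), "unknown sample")
})

test_that("variable-gene selection finds planted high-variance genes and
           breaks ties lexicographically", {
  set.seed(11)
  n <- 100
  vals <- matrix(2^rnorm(n * 20, 5, 0.05), nrow = n,
                 dimnames = list(sprintf("g%03d", 1:n), paste0("s", 1:20)))
  planted <- c("g005", "g020", "g050", "g080", "g099")
  vals[planted, ] <- 2^rnorm(5 * 20, 5, 3)
  m <- expr_matrix(vals, state = "cpm")
  expect_setequal(select_variable_genes(list(m), 5), planted)
  expect_length(select_variable_genes(list(m), 1000), n)
  expect_error(select_variable_genes(list(m), 0), "positive")

  tie <- expr_matrix(matrix(c(1, 2, 1, 2, 2, 1, 2, 1), nrow = 4,
                            dimnames = list(c("zz", "aa", "mm", "bb"), c("s1", "s2"))),
                     state = "cpm")
  # all four genes tie on variance; lexicographic order decides
  expect_identical(select_variable_genes(list(tie), 2), c("aa", "bb"))
})

test_that("pseudo-sample expansion splits multi-target samples and
           preserves the row-count identity", {
  path <- write_raw_tsv(c(
    "sample_id\tpatient_id\trole\tcancer_type\torigin_tissue\ttarget_tissues",
    "m1\tpa\tmetastatic\tBRCA\tbreast\tliver;lung;brain",
    "p1\tpa\tprimary\tBRCA\tbreast\tliver",
    "n1\t\tnormal\t\tbreast\t"))
  ann <- read_sample_annotation(path)
  out <- expand_pseudo_samples(ann)
  expect_equal(nrow(out), sum(pmax(1, lengths(ann$target_tissues))))
  m1_rows <- out[out$source_sample_id == "m1", ]
  expect_identical(m1_rows$sample_id, c("m1::liver", "m1::lung", "m1::brain"))
  expect_identical(unlist(m1_rows$target_tissues), c("liver", "lung", "brain"))
  expect_identical(out$sample_id[out$source_sample_id == "p1"], "p1")
  # normals with no target pass silently; tumors with none warn
  expect_silent(expand_pseudo_samples(ann[3, ]))
  ann_no_tt <- ann
  ann_no_tt$target_tissues[[2]] <- character()
  expect_warning(expand_pseudo_samples(ann_no_tt), "no target tissue")
})
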
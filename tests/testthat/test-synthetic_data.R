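test_that("the generator is fully determined by its seed", {
  cfg <- simulation_config(n_genes = 150, tissues = c("colon", "liver"),
                           n_normals = 4, n_patients = 4, seed = 71)
  a <- generate_reference_cohort(cfg)
  b <- generate_reference_cohort(cfg)
  expect_identical(mat_values(a$matrix), mat_values(b$matrix))
  ta <- generate_tumor_cohort(cfg, a, "colon", "liver")
  tb <- generate_tumor_cohort(cfg, b, "colon", "liver")
  expect_identical(mat_values(ta$matrix), mat_values(tb$matrix))
})

test_that("zero tissue separation collapses median profiles while
           separated tissues stay apart", {
  cfg <- simulation_config(
    n_genes = 2000, tissues = c("t1", "t2", "t3"),
    separation = c(t1 = 0, t2 = 0, t3 = 1.5),
    sparsity = 0, n_normals = 15, seed = 72)
  ref <- generate_reference_cohort(cfg)
  profs <- lapply(setNames(cfg$tissues, cfg$tissues), function(t) {
    build_reference_profile(
      ref$matrix, ref$annotation$sample_id[ref$annotation$origin_tissue == t],
      tissue = t)
  })
  d12 <- transcriptomic_distance(as.numeric(profs$t1), profs$t2)
  d13 <- transcriptomic_distance(as.numeric(profs$t1), profs$t3)
  d23 <- transcriptomic_distance(as.numeric(profs$t2), profs$t3)
  expect_lt(d12, d13)
  expect_lt(d12, d23)
})

test_that("one sample per tissue makes the reference equal the sample", {
  cfg <- simulation_config(n_genes = 100, tissues = c("colon", "liver"),
                           n_normals = 1, seed = 73)
  ref <- generate_reference_cohort(cfg)
  prof <- build_reference_profile(ref$matrix, "colon_n01", tissue = "colon")
  expect_equal(as.numeric(prof), mat_values(ref$matrix)[, "colon_n01"],
               ignore_attr = TRUE)
})

test_that("a noiseless, offset-free, alpha = 0 cohort collapses onto the
           origin tissue with TD ratio 0", {
  cfg <- simulation_config(n_genes = 200, tissues = c("colon", "liver"),
                           n_normals = 3, n_patients = 3, noise_sd = 0,
                           tumor_offset = 0, alpha_primary = 0, alpha_met = 0,
                           seed = 74)
  ref <- generate_reference_cohort(cfg)
  tum <- generate_tumor_cohort(cfg, ref, "colon", "liver")
  refs <- lapply(setNames(cfg$tissues, cfg$tissues), function(t) {
    build_reference_profile(
      ref$matrix, ref$annotation$sample_id[ref$annotation$origin_tissue == t],
      tissue = t)
  })
  td <- cohort_td_ratios(tum$matrix, tum$annotation, refs)
  expect_equal(td$ratio, rep(0, nrow(td)))
})

test_that("paired cohorts pair every metastasis with a primary and
           unpaired ones do not", {
  cfg <- simulation_config(n_genes = 100, tissues = c("colon", "liver"),
                           n_normals = 3, n_patients = 6, seed = 75)
  ref <- generate_reference_cohort(cfg)
  paired <- generate_tumor_cohort(cfg, ref, "colon", "liver")$annotation
  mets <- paired[paired$role == "metastatic", ]
  pris <- paired[paired$role == "primary", ]
  expect_true(all(mets$patient_id %in% pris$patient_id))
  unpaired <- generate_tumor_cohort(cfg, ref, "colon", "liver",
                                    paired = FALSE)$annotation
  expect_length(intersect(unpaired$patient_id[unpaired$role == "metastatic"],
                          unpaired$patient_id[unpaired$role == "primary"]), 0)
})

test_that("planting a shift only redraws the planted genes and errors on
           unknown genes", {
  cfg <- simulation_config(n_genes = 200, tissues = c("colon", "liver"),
                           n_normals = 3, n_patients = 4, seed = 76)
  ref <- generate_reference_cohort(cfg)
  tum <- generate_tumor_cohort(cfg, ref, "colon", "liver")
  set <- rownames(ref$mu)[11:30]
  planted <- plant_pathway_shift(tum, set, alpha_p = 0.9, seed = 77)
  changed <- mat_values(planted$matrix) != mat_values(tum$matrix)
  expect_true(all(rownames(tum$matrix)[rowSums(changed) > 0] %in% set))
  expect_equal(mat_values(planted$matrix)[!rownames(tum$matrix) %in% set, ],
               mat_values(tum$matrix)[!rownames(tum$matrix) %in% set, ])
  expect_named(planted$truth$planted, "planted_1")
  expect_error(plant_pathway_shift(tum, c("nope", set), 0.9), "unknown gene")
  expect_error(plant_pathway_shift(tum, set, 1.5), "\\[0, 1\\]")
})

test_that("generated gene sets respect size bounds, uniqueness, and the
           seed", {
  genes <- sprintf("g%03d", 1:80)
  a <- generate_gene_sets(genes, 12, c(5, 15), seed = 78)
  b <- generate_gene_sets(genes, 12, c(5, 15), seed = 78)
  expect_identical(a, b)
  expect_true(all(lengths(a) >= 5 & lengths(a) <= 15))
  for (s in a) expect_false(anyDuplicated(s) > 0)
  expect_error(generate_gene_sets(genes, 3, c(5, 100)), "exceeds")
})

test_that("purity mixing plants a detectable ratio-purity association", {
  hits <- vapply(1:10, function(i) {
    cfg <- simulation_config(n_genes = 500, tissues = c("colon", "liver"),
                             n_normals = 8, n_patients = 25,
                             purity_mixing = TRUE, seed = 100 + i)
    ref <- generate_reference_cohort(cfg)
    tum <- generate_tumor_cohort(cfg, ref, "colon", "liver")
    refs <- lapply(setNames(cfg$tissues, cfg$tissues), function(t) {
      build_reference_profile(
        ref$matrix, ref$annotation$sample_id[ref$annotation$origin_tissue == t],
        tissue = t)
    })
    td <- cohort_td_ratios(tum$matrix, tum$annotation, refs)
    pur <- tum$annotation$purity[match(td$sample_id, tum$annotation$sample_id)]
    assoc <- purity_association(td$ratio, pur)
    assoc$p < 0.05 && assoc$rho > 0
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("fixture bundles round-trip through the readers and list the
           planted pathways", {
  cfg <- simulation_config(n_genes = 120, tissues = c("colon", "liver"),
                           n_normals = 3, n_patients = 4, seed = 79)
  dir_a <- file.path(tempdir(), "bundle_a")
  bundle <- write_fixture_bundle(cfg, dir_a, n_sets = 5, n_planted = 2)
  m <- read_expression_matrix(bundle$tumor_matrix, state = "cpm")
  expect_equal(mat_values(m), mat_values(bundle$objects$tumor$matrix),
               tolerance = 1e-12)
  ann <- read_sample_annotation(bundle$annotation)
  expect_setequal(ann$sample_id,
                  c(bundle$objects$reference$annotation$sample_id,
                    bundle$objects$tumor$annotation$sample_id))
  truth <- yaml::read_yaml(bundle$ground_truth)
  expect_identical(unlist(truth$planted_pathways), bundle$objects$planted)

  dir_b <- file.path(tempdir(), "bundle_b")
  write_fixture_bundle(cfg, dir_b, n_sets = 5, n_planted = 2)
  expect_identical(readLines(bundle$tumor_matrix),
                   readLines(file.path(dir_b, "tumor_expression.tsv")))
})
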
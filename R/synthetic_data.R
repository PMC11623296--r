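#' Configuration for the synthetic cohort generator
#'
#' The generator draws lognormal expression: each tissue has a per-gene
#' log2 mean equal to a shared baseline plus `separation` times a
#' tissue-specific standard-normal displacement, with a `sparsity`
#' fraction of tissue-specifically silenced genes. Tumor samples mix the
#' origin- and target-tissue log-means with weight `alpha`
#' (`(1 - alpha) * OT + alpha * TT`) plus a cohort-level tumor-specific
#' offset, plus per-sample Gaussian noise on the log scale. Optional
#' purity confounding mixes each observed tumor sample with the clean OT
#' profile on the linear scale: `observed = purity * tumor +
#' (1 - purity) * OT`, `purity ~ Beta(shape1, shape2)`.
#'
#' @param n_genes Number of genes.
#' @param tissues Tissue names.
#' @param separation Log2-scale mean displacement scale per tissue;
#'   scalar or named per-tissue vector. 0 makes tissues identical in
#'   expectation.
#' @param sparsity Fraction of genes silenced per tissue.
#' @param n_normals Normal samples per tissue.
#' @param n_patients Tumor patients per cohort.
#' @param paired Whether each patient contributes a primary and a
#'   metastatic sample.
#' @param alpha_primary,alpha_met Mixture weights toward the target
#'   tissue for primary and metastatic samples (metastases shifted
#'   further by default).
#' @param tumor_offset Scale of the cohort-level tumor-specific log2
#'   offset shared by all samples of the cohort.
#' @param noise_sd Per-sample log2 noise standard deviation (0 gives
#'   noiseless, degenerate cohorts; supported for identity checks).
#' @param purity_mixing Whether to apply purity confounding.
#' @param purity_shape1,purity_shape2 Beta parameters of the purity draw.
#' @param base_log_mean,base_log_sd Baseline log2 mean distribution.
#' @param seed Integer seed; fully determines generator output.
#' @return List of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000,
                              tissues = c("colon", "liver", "lung", "brain", "ovary", "skin"),
                              separation = 1,
                              sparsity = 0.1,
                              n_normals = 20,
                              n_patients = 20,
                              paired = TRUE,
                              alpha_primary = 0.15,
                              alpha_met = 0.45,
                              tumor_offset = 0.5,
                              noise_sd = 0.5,
                              purity_mixing = FALSE,
                              purity_shape1 = 6,
                              purity_shape2 = 2,
                              base_log_mean = 5,
                              base_log_sd = 2,
                              seed = 1206) {
  stopifnot(n_genes >= 2, length(tissues) >= 1, !anyDuplicated(tissues))
  if (alpha_primary < 0 || alpha_primary > 1 || alpha_met < 0 || alpha_met > 1) {
    stop("mixture weights must lie in [0, 1]")
  }
  if (any(separation < 0)) stop("separation must be >= 0")
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  sep <- if (length(separation) == 1) {
    stats::setNames(rep(separation, length(tissues)), tissues)
  } else {
    if (!all(tissues %in% names(separation))) {
      stop("per-tissue separation must be named for every tissue")
    }
    separation[tissues]
  }
  structure(list(n_genes = n_genes, tissues = tissues, separation = sep,
                 sparsity = sparsity, n_normals = n_normals,
                 n_patients = n_patients, paired = paired,
                 alpha_primary = alpha_primary, alpha_met = alpha_met,
                 tumor_offset = tumor_offset, noise_sd = noise_sd,
                 purity_mixing = purity_mixing,
                 purity_shape1 = purity_shape1, purity_shape2 = purity_shape2,
                 base_log_mean = base_log_mean, base_log_sd = base_log_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Run expr with the RNG seeded locally, restoring global state afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate the normal reference cohort for every configured tissue
#'
#' @param cfg A [simulation_config()].
#' @return List: `matrix` (linear-scale [expr_matrix()]), `annotation`,
#'   and `mu` (the latent gene x tissue log2-mean matrix, the generator's
#'   ground truth).
#' @export
generate_reference_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    shared <- stats::rnorm(cfg$n_genes, cfg$base_log_mean, cfg$base_log_sd)
    mu <- sapply(cfg$tissues, function(t) {
      m <- shared + cfg$separation[[t]] * stats::rnorm(cfg$n_genes)
      if (cfg$sparsity > 0) {
        silenced <- sample.int(cfg$n_genes, floor(cfg$sparsity * cfg$n_genes))
        m[silenced] <- 0
      }
      m
    })
    rownames(mu) <- genes
    cols <- list(); ids <- character(); tiss <- character()
    for (t in cfg$tissues) {
      for (i in seq_len(cfg$n_normals)) {
        l <- mu[, t] + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd)
        cols[[length(cols) + 1]] <- 2^l
        ids <- c(ids, sprintf("%s_n%02d", t, i))
        tiss <- c(tiss, t)
      }
    }
    vals <- do.call(cbind, cols)
    dimnames(vals) <- list(genes, ids)
    ann <- data.frame(sample_id = ids, patient_id = NA_character_,
                      role = "normal", cancer_type = NA_character_,
                      origin_tissue = tiss, stringsAsFactors = FALSE)
    ann$target_tissues <- I(rep(list(character()), nrow(ann)))
    ann$purity <- NA_real_
    list(matrix = expr_matrix(vals, state = "cpm"), annotation = ann, mu = mu)
  })
}

#' Generate a paired or unpaired tumor cohort for one (OT, TT) pair
#'
#' @param cfg A [simulation_config()].
#' @param ref Reference cohort from [generate_reference_cohort()]
#'   (supplies the latent tissue log-means).
#' @param ot,tt Origin and target tissue names (must be configured
#'   tissues).
#' @param cancer_type Label recorded in the annotation.
#' @param alpha_primary,alpha_met,n_patients,paired Optional overrides of
#'   the config values.
#' @param seed Seed for the cohort draw; defaults to `cfg$seed + 1000` so
#'   reference and tumor draws are decoupled but reproducible.
#' @return List: `matrix`, `annotation`, `truth` (latent parameters:
#'   `mu_ot`, `mu_tt`, `tumor_effect`, mixture weights, purity slopes,
#'   planted pathways).
#' @export
generate_tumor_cohort <- function(cfg, ref, ot, tt,
                                  cancer_type = paste0(ot, "_ca"),
                                  alpha_primary = cfg$alpha_primary,
                                  alpha_met = cfg$alpha_met,
                                  n_patients = cfg$n_patients,
                                  paired = cfg$paired,
                                  seed = cfg$seed + 1000L) {
  stopifnot(inherits(cfg, "sim_config"))
  for (t in c(ot, tt)) {
    if (!t %in% colnames(ref$mu)) stop("tissue '", t, "' not in reference cohort")
  }
  if (alpha_primary < 0 || alpha_primary > 1 || alpha_met < 0 || alpha_met > 1) {
    stop("mixture weights must lie in [0, 1]")
  }
  .with_seed(seed, {
    genes <- rownames(ref$mu)
    n_genes <- length(genes)
    mu_ot <- ref$mu[, ot]
    mu_tt <- ref$mu[, tt]
    tumor_effect <- cfg$tumor_offset * stats::rnorm(n_genes)
    draw <- function(alpha) {
      lmean <- (1 - alpha) * mu_ot + alpha * mu_tt + tumor_effect
      2^(lmean + stats::rnorm(n_genes, 0, cfg$noise_sd))
    }
    cols <- list(); ids <- character(); roles <- character(); pats <- character()
    for (i in seq_len(n_patients)) {
      pid <- sprintf("%s_p%03d", cancer_type, i)
      if (paired || i <= ceiling(n_patients / 2)) {
        cols[[length(cols) + 1]] <- draw(alpha_primary)
        ids <- c(ids, paste0(pid, "_pri")); roles <- c(roles, "primary")
        pats <- c(pats, pid)
      }
      if (paired || i > ceiling(n_patients / 2)) {
        cols[[length(cols) + 1]] <- draw(alpha_met)
        ids <- c(ids, paste0(pid, "_met")); roles <- c(roles, "metastatic")
        pats <- c(pats, pid)
      }
    }
    vals <- do.call(cbind, cols)
    dimnames(vals) <- list(genes, ids)
    purity <- rep(NA_real_, length(ids))
    if (cfg$purity_mixing) {
      purity <- stats::rbeta(length(ids), cfg$purity_shape1, cfg$purity_shape2)
      ot_clean <- 2^mu_ot
      for (j in seq_along(ids)) {
        vals[, j] <- purity[j] * vals[, j] + (1 - purity[j]) * ot_clean
      }
    }
    ann <- data.frame(sample_id = ids, patient_id = pats, role = roles,
                      cancer_type = cancer_type, origin_tissue = ot,
                      stringsAsFactors = FALSE)
    ann$target_tissues <- I(rep(list(tt), nrow(ann)))
    ann$purity <- purity
    list(matrix = expr_matrix(vals, state = "cpm"), annotation = ann,
         truth = list(ot = ot, tt = tt, mu_ot = mu_ot, mu_tt = mu_tt,
                      tumor_effect = tumor_effect,
                      alpha_primary = alpha_primary, alpha_met = alpha_met,
                      noise_sd = cfg$noise_sd,
                      purity_mixing = cfg$purity_mixing,
                      planted = list()))
  })
}

#' Plant a pathway-level expression shift into a tumor cohort
#'
#' Re-draws only the given genes of every tumor sample with mixture
#' weight `alpha_p` toward the target tissue (other genes untouched),
#' re-applying the sample's purity mixing if the cohort was generated
#' with it. This is the ground truth for pathway-level delta-ratio
#' recovery.
#'
#' @param cohort Tumor cohort from [generate_tumor_cohort()].
#' @param gene_set Character vector of genes to shift (must exist).
#' @param alpha_p Mixture weight for the planted genes.
#' @param name Pathway name recorded in `truth$planted`.
#' @param seed Seed for the redraw.
#' @return The cohort with modified matrix and updated `truth$planted`.
#' @export
plant_pathway_shift <- function(cohort, gene_set, alpha_p,
                                name = paste0("planted_", length(cohort$truth$planted) + 1),
                                seed = NULL) {
  if (alpha_p < 0 || alpha_p > 1) stop("alpha_p must lie in [0, 1]")
  unknown <- setdiff(gene_set, rownames(cohort$matrix))
  if (length(unknown)) {
    stop("unknown gene(s) in set: ", paste(utils::head(unknown, 5), collapse = ", "))
  }
  tr <- cohort$truth
  .with_seed(seed, {
    idx <- match(gene_set, rownames(cohort$matrix))
    lmean <- (1 - alpha_p) * tr$mu_ot[idx] + alpha_p * tr$mu_tt[idx] +
      tr$tumor_effect[idx]
    vals <- unclass(cohort$matrix)[, , drop = FALSE]
    ann <- cohort$annotation
    for (j in seq_len(ncol(vals))) {
      fresh <- 2^(lmean + stats::rnorm(length(idx), 0, tr$noise_sd))
      if (tr$purity_mixing && !is.na(ann$purity[j])) {
        fresh <- ann$purity[j] * fresh + (1 - ann$purity[j]) * 2^tr$mu_ot[idx]
      }
      vals[idx, j] <- fresh
    }
    cohort$matrix <- expr_matrix(vals, state = expr_state(cohort$matrix))
    cohort$truth$planted[[name]] <- list(genes = gene_set, alpha_p = alpha_p)
    cohort
  })
}

#' Generate reproducible random gene sets for null calibration
#'
#' @param genes Gene universe.
#' @param n_sets Number of sets.
#' @param size_range Length-2 integer range of set sizes (inclusive).
#' @param seed Seed.
#' @param prefix Name prefix.
#' @return Named list of character vectors.
#' @export
generate_gene_sets <- function(genes, n_sets, size_range = c(25, 100),
                               seed = NULL, prefix = "SET") {
  if (max(size_range) > length(genes)) stop("size_range exceeds gene count")
  if (min(size_range) < 1) stop("set sizes must be >= 1")
  .with_seed(seed, {
    pool <- seq(min(size_range), max(size_range))
    sizes <- pool[sample.int(length(pool), n_sets, replace = TRUE)]
    sets <- lapply(sizes, function(s) sample(genes, s))
    stats::setNames(sets, sprintf("%s_%03d", prefix, seq_len(n_sets)))
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Emits the normal reference matrix, a tumor cohort for the first two
#' configured tissues (with planted pathway shifts), annotations, gene
#' sets (GMT) and a ground-truth YAML listing the latent parameters, so
#' the whole pipeline can run from files alone.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param n_sets Number of gene sets to emit.
#' @param n_planted How many of them get a planted shift.
#' @param alpha_planted Mixture weight of the planted shift.
#' @return Named list of file paths, invisibly; also the in-memory
#'   objects under `$objects`.
#' @export
write_fixture_bundle <- function(cfg, out_dir, n_sets = 20, n_planted = 3,
                                 alpha_planted = 0.9) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- generate_reference_cohort(cfg)
  ot <- cfg$tissues[1]; tt <- cfg$tissues[2]
  tumor <- generate_tumor_cohort(cfg, ref, ot, tt)
  sets <- generate_gene_sets(rownames(ref$mu), n_sets,
                             size_range = c(25, min(100, cfg$n_genes)),
                             seed = cfg$seed + 2000L)
  planted <- character()
  if (n_planted > 0) {
    planted <- names(sets)[seq_len(n_planted)]
    for (k in seq_len(n_planted)) {
      tumor <- plant_pathway_shift(tumor, sets[[k]], alpha_planted,
                                   name = names(sets)[k],
                                   seed = cfg$seed + 3000L + k)
    }
  }
  paths <- list(
    normal_matrix = file.path(out_dir, "normal_expression.tsv"),
    tumor_matrix = file.path(out_dir, "tumor_expression.tsv"),
    annotation = file.path(out_dir, "sample_annotation.tsv"),
    gene_sets = file.path(out_dir, "gene_sets.gmt"),
    ground_truth = file.path(out_dir, "ground_truth.yml")
  )
  write_expression_matrix(ref$matrix, paths$normal_matrix)
  write_expression_matrix(tumor$matrix, paths$tumor_matrix)
  write_sample_annotation(rbind(ref$annotation, tumor$annotation),
                          paths$annotation)
  write_gene_sets_gmt(sets, paths$gene_sets)
  yaml::write_yaml(list(
    seed = cfg$seed,
    ot = ot, tt = tt,
    alpha_primary = cfg$alpha_primary, alpha_met = cfg$alpha_met,
    noise_sd = cfg$noise_sd, separation = as.list(cfg$separation),
    purity_mixing = cfg$purity_mixing,
    planted_pathways = as.list(planted),
    alpha_planted = if (length(planted)) alpha_planted else NULL
  ), paths$ground_truth)
  out <- paths
  out$objects <- list(reference = ref, tumor = tumor, gene_sets = sets,
                      planted = planted)
  invisible(out)
}
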
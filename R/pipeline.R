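#' Summarize TD ratios by group with paired or unpaired one-sided tests
#'
#' For every (cancer type, target tissue) with both classes present,
#' tests whether the metastatic TD ratios (residuals, when a `residual`
#' column is present) exceed the primary ones: a one-sided signed-rank
#' test across patients when >= 3 pairs exist, otherwise a one-sided
#' rank-sum test when each class has >= 3 samples. Also reports the raw
#' distance-to-target comparison in the opposite direction (metastases
#' closer to the target tissue). BH FDR across comparisons; groups too
#' small for either test are kept with a skip reason.
#'
#' @param td Table from [cohort_td_ratios()] (optionally with a
#'   `residual` column).
#' @param alpha FDR threshold for the reported `significant` flag.
#' @return Data frame per comparison: group key, sample counts, medians,
#'   test used, `p`, `fdr`, `td_tt_p` (distance comparison), skip reason.
#' @export
summarize_groups <- function(td, alpha = 0.1) {
  value <- if ("residual" %in% colnames(td)) td$residual else td$ratio
  td$.value <- value
  td <- td[is.finite(td$.value), , drop = FALSE]
  keys <- split(seq_len(nrow(td)),
                interaction(td$cancer_type, td$target_tissue, drop = TRUE))
  rows <- list()
  for (ii in keys) {
    g <- td[ii, , drop = FALSE]
    pri <- g[g$role == "primary", , drop = FALSE]
    met <- g[g$role == "metastatic", , drop = FALSE]
    base <- data.frame(cancer_type = g$cancer_type[1],
                       target_tissue = g$target_tissue[1],
                       n_primary = nrow(pri), n_metastatic = nrow(met),
                       median_primary = stats::median(pri$.value),
                       median_metastatic = stats::median(met$.value),
                       stringsAsFactors = FALSE)
    if (!nrow(pri) || !nrow(met)) next
    shared <- intersect(pri$patient_id[!is.na(pri$patient_id)],
                        met$patient_id[!is.na(met$patient_id)])
    if (length(shared) >= 3) {
      mp <- met$.value[match(shared, met$patient_id)]
      pp <- pri$.value[match(shared, pri$patient_id)]
      d <- mp - pp
      ht <- if (all(d == 0)) list(p = 1, method = "signed_rank_exact") else
        suppressMessages(wilcoxon_signed_rank(d[d != 0], alternative = "greater"))
      dtt <- met$td_tt[match(shared, met$patient_id)] -
        pri$td_tt[match(shared, pri$patient_id)]
      ht_tt <- if (all(dtt == 0)) list(p = 1) else
        suppressMessages(wilcoxon_signed_rank(dtt[dtt != 0], alternative = "less"))
      rows[[length(rows) + 1]] <- cbind(base, data.frame(
        method = ht$method, n_pairs = length(shared), p = ht$p,
        td_tt_p = ht_tt$p, skipped = NA_character_, stringsAsFactors = FALSE))
    } else if (nrow(pri) >= 3 && nrow(met) >= 3) {
      ht <- wilcoxon_rank_sum(met$.value, pri$.value, alternative = "greater")
      ht_tt <- wilcoxon_rank_sum(met$td_tt, pri$td_tt, alternative = "less")
      rows[[length(rows) + 1]] <- cbind(base, data.frame(
        method = ht$method, n_pairs = NA_integer_, p = ht$p,
        td_tt_p = ht_tt$p, skipped = NA_character_, stringsAsFactors = FALSE))
    } else {
      rows[[length(rows) + 1]] <- cbind(base, data.frame(
        method = NA_character_, n_pairs = length(shared), p = NA_real_,
        td_tt_p = NA_real_,
        skipped = "fewer than 3 pairs and fewer than 3 samples per class",
        stringsAsFactors = FALSE))
    }
  }
  if (!length(rows)) stop("no valid comparison groups")
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out$significant <- !is.na(out$fdr) & out$fdr < alpha
  out$direction <- ifelse(is.na(out$p), NA_character_,
                          ifelse(out$median_metastatic > out$median_primary,
                                 "metastatic_greater", "primary_greater"))
  rownames(out) <- NULL
  out
}

# Apply the purity decision rule: test ratio ~ purity within each class;
# if either class is significant (p < 0.05), residualize the dataset's
# ratios pooling both classes and add a `residual` column.
.apply_purity_adjustment <- function(td, ann, p_threshold = 0.05) {
  pur <- ann$purity[match(td$sample_id, ann$sample_id)]
  info <- list(tested = FALSE, adjusted = FALSE, by_class = list())
  usable <- is.finite(td$ratio) & is.finite(pur)
  if (sum(usable) < 3 || all(is.na(pur))) {
    return(list(td = td, info = info))
  }
  info$tested <- TRUE
  trigger <- FALSE
  for (cls in intersect(c("primary", "metastatic"), unique(td$role))) {
    sel <- usable & td$role == cls
    if (sum(sel) >= 3 && stats::sd(pur[sel]) > 0) {
      assoc <- purity_association(td$ratio[sel], pur[sel])
      info$by_class[[cls]] <- assoc[c("rho", "p", "n")]
      if (is.finite(assoc$p) && assoc$p < p_threshold) trigger <- TRUE
    }
  }
  if (trigger) {
    td$residual <- NA_real_
    td$residual[usable] <- purity_residualize(td$ratio[usable], pur[usable])
    info$adjusted <- TRUE
  }
  list(td = td, info = info)
}

#' Run the full transcriptomic-distance analysis from a configuration
#'
#' Stages, in order: read inputs, harmonize genes, build per-tissue
#' reference profiles, per-sample TD ratios with the purity decision
#' rule, group summaries, specificity analysis, pathway-level empirical
#' p-values (TD ratio and, when pairs exist, PMT score), and hallmark
#' enrichment (geometric-mean fold change + pre-ranked enrichment and
#' single-sample activity comparison). All outputs are written as TSV
#' next to a YAML run manifest recording seeds and parameters.
#'
#' @param config Named list or path to a YAML file with entries:
#'   `tumor_matrix`, `normal_matrix`, `annotation`, `gene_sets` (paths);
#'   optional `tumor_state`/`normal_state` (default `"cpm"`), `measure`
#'   (`"euclidean"`), `reference_statistic` (`"median"`),
#'   `overlap_threshold` (0.9), `min_group_size` (3), `n_iter` (10000),
#'   `fdr_threshold` (0.1), `n_perm` (2000), `stages` (subset of
#'   `c("td", "specificity", "pathways", "enrichment")`).
#' @param out_dir Output directory.
#' @param seed Integer seed for all randomized stages.
#' @return Invisibly, a list with every result table and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = 1206) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(tumor_state = "cpm", normal_state = "cpm",
                   measure = "euclidean", reference_statistic = "median",
                   overlap_threshold = 0.9, min_group_size = 3,
                   n_iter = 10000, n_perm = 2000, fdr_threshold = 0.1,
                   stages = c("td", "specificity", "pathways", "enrichment"))
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  for (nm in c("tumor_matrix", "normal_matrix", "annotation", "gene_sets")) {
    if (is.null(config[[nm]])) stop("config is missing '", nm, "'")
    if (!file.exists(config[[nm]])) {
      stop("stage io failed: file not found: ", config[[nm]])
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    on.exit(message(sprintf("[%s] %.1fs", name,
                            as.numeric(difftime(Sys.time(), t0, units = "secs")))))
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  res <- list()

  dat <- stage("io", {
    tumor <- read_expression_matrix(config$tumor_matrix, state = config$tumor_state)
    normal <- read_expression_matrix(config$normal_matrix, state = config$normal_state)
    ann <- read_sample_annotation(config$annotation)
    sets <- read_gene_sets_gmt(config$gene_sets)
    hm <- harmonize_genes(list(tumor = tumor, normal = normal))
    list(tumor = hm$tumor, normal = hm$normal,
         ann = expand_pseudo_samples(ann), sets = sets)
  })
  refs <- stage("references", {
    norm_ann <- dat$ann[dat$ann$role == "normal", , drop = FALSE]
    tissues <- unique(norm_ann$origin_tissue)
    stats::setNames(lapply(tissues, function(t) {
      build_reference_profile(dat$normal,
                              norm_ann$sample_id[norm_ann$origin_tissue == t],
                              statistic = config$reference_statistic,
                              tissue = t)
    }), tissues)
  })

  if ("td" %in% config$stages) {
    adj <- stage("td_ratios", {
      td <- cohort_td_ratios(dat$tumor, dat$ann, refs, measure = config$measure)
      .apply_purity_adjustment(td, dat$ann)
    })
    res$purity <- adj$info
    res$td_ratios <- adj$td
    res$group_summary <- stage("group_summary", {
      summarize_groups(res$td_ratios, alpha = config$fdr_threshold)
    })
    utils::write.table(res$td_ratios, file.path(out_dir, "td_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(res$group_summary, file.path(out_dir, "group_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if ("specificity" %in% config$stages) {
    res$specificity <- stage("specificity", {
      tum <- dat$ann[dat$ann$role == "metastatic", , drop = FALSE]
      out <- list()
      for (key in unique(paste(tum$cancer_type,
                               vapply(tum$target_tissues, `[[`, "", 1)))) {
        sel <- paste(tum$cancer_type,
                     vapply(tum$target_tissues, `[[`, "", 1)) == key
        ids <- tum$sample_id[sel]
        if (length(ids) < 3) next
        ot <- tum$origin_tissue[sel][1]
        tt <- tum$target_tissues[sel][[1]][1]
        cands <- refs[setdiff(names(refs), ot)]
        if (length(cands) < 2 || !tt %in% names(cands)) next
        src <- if ("source_sample_id" %in% colnames(tum)) tum$source_sample_id[sel] else ids
        out[[key]] <- specificity_analysis(dat$tumor, src, refs[[ot]], cands,
                                           true_tt = tt,
                                           measure = config$measure,
                                           alpha = config$fdr_threshold)
      }
      out
    })
    if (length(res$specificity)) {
      spec_tab <- do.call(rbind, lapply(names(res$specificity), function(k) {
        cbind(group = k, res$specificity[[k]]$table,
              score = res$specificity[[k]]$score)
      }))
      utils::write.table(spec_tab, file.path(out_dir, "specificity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("pathways" %in% config$stages) {
    res$pathway_td <- stage("pathway_td_ratios", {
      pathway_analysis(dat$tumor, dat$ann, refs, dat$sets,
                       value_kind = "td_ratio", measure = config$measure,
                       overlap_threshold = config$overlap_threshold,
                       min_group_size = config$min_group_size,
                       n_iter = config$n_iter, seed = seed,
                       alpha = config$fdr_threshold)
    })
    utils::write.table(res$pathway_td, file.path(out_dir, "pathway_td_ratios.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    has_pairs <- any(dat$ann$role == "metastatic" & !is.na(dat$ann$patient_id) &
                       dat$ann$patient_id %in%
                         dat$ann$patient_id[dat$ann$role == "primary"])
    if (has_pairs) {
      res$pathway_pmt <- stage("pathway_pmt_scores", {
        pathway_analysis(dat$tumor, dat$ann, refs, dat$sets,
                         value_kind = "pmt_score", measure = "euclidean",
                         overlap_threshold = config$overlap_threshold,
                         min_group_size = config$min_group_size,
                         n_iter = config$n_iter, seed = seed + 1L,
                         alpha = config$fdr_threshold)
      })
      utils::write.table(res$pathway_pmt,
                         file.path(out_dir, "pathway_pmt_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("enrichment" %in% config$stages) {
    res$enrichment <- stage("enrichment", {
      ann <- dat$ann
      pri_ids <- ann$sample_id[ann$role == "primary"]
      met_ids <- ann$sample_id[ann$role == "metastatic"]
      if (length(pri_ids) && length(met_ids)) {
        fc <- geometric_log2_fold_change(dat$tumor[, pri_ids],
                                         dat$tumor[, met_ids])
        gsea <- preranked_gsea(fc, dat$sets, n_perm = config$n_perm,
                               seed = seed + 2L)
        act <- single_sample_activity(dat$tumor, dat$sets)
        groups <- stats::setNames(ann$role, ann$sample_id)
        cmp <- compare_group_activity(act, groups[c(pri_ids, met_ids)])
        list(fold_changes = fc, gsea = gsea, activity = act,
             activity_comparison = cmp)
      } else NULL
    })
    if (!is.null(res$enrichment)) {
      utils::write.table(res$enrichment$gsea, file.path(out_dir, "gsea.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(res$enrichment$activity_comparison,
                         file.path(out_dir, "activity_comparison.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tdratio")),
    seed = seed,
    config = config[setdiff(names(config), "stages")],
    stages = config$stages,
    n_genes = nrow(dat$tumor),
    n_tumor_samples = ncol(dat$tumor),
    n_normal_samples = ncol(dat$normal),
    purity = res$purity
  )
  yaml::write_yaml(manifest, file.path(out_dir, "run_manifest.yml"))
  res$manifest <- manifest
  invisible(res)
}
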
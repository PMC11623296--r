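#' Construct an expression matrix with a declared normalization state
#'
#' The pipeline's canonical expression container: a numeric gene x sample
#' matrix tagged with the normalization state of its values. Values are on a
#' linear scale unless `state = "log_space"`, and state changes only through
#' [normalize_counts()].
#'
#' @param values Numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample ids).
#' @param state One of `"counts"`, `"cpm"`, `"tmm_cpm"`, `"uq"`,
#'   `"log_space"`.
#' @return A matrix of class `expr_matrix` with a `state` attribute.
#' @export
expr_matrix <- function(values,
                        state = c("counts", "cpm", "tmm_cpm", "uq", "log_space")) {
  state <- match.arg(state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (state != "log_space" && any(values < 0)) {
    stop("negative values are not allowed when state = '", state, "'")
  }
  structure(values, class = c("expr_matrix", "matrix", "array"), state = state)
}

#' @rdname expr_matrix
#' @param m An `expr_matrix`.
#' @export
expr_state <- function(m) {
  s <- attr(m, "state")
  if (is.null(s)) stop("not an expr_matrix: no state attribute")
  s
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  st <- attr(x, "state")
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) out <- structure(out, class = class(x), state = st)
  out
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples, state = %s\n",
              nrow(x), ncol(x), expr_state(x)))
  invisible(x)
}

#' Read a gene x sample expression matrix from tab-separated text
#'
#' First column holds gene symbols, the header row holds sample ids.
#' Duplicate gene rows are collapsed by their mean with a warning; duplicate
#' sample ids and non-numeric cells are hard errors.
#'
#' @param path Path to a TSV file.
#' @param state Declared normalization state of the stored values.
#' @return An [expr_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   state = c("counts", "cpm", "tmm_cpm", "uq", "log_space")) {
  state <- match.arg(state)
  if (!file.exists(path)) stop("cannot read expression matrix: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2) stop("expression TSV needs a gene column and >= 1 sample column")
  genes <- tab[[1]]
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(NULL, samples)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell '%s' at gene '%s', sample '%s' in %s",
                 vals[bad[1], bad[2]], genes[bad[1]], samples[bad[2]], path))
  }
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("collapsing ", length(dup), " duplicated gene symbol(s) by mean: ",
            paste(utils::head(dup, 5), collapse = ", "),
            if (length(dup) > 5) ", ..." else "")
    num <- rowsum(num, group = genes) / as.vector(table(genes)[unique(genes)])
    # rowsum orders by group; restore first-occurrence order
    num <- num[match(unique(genes), rownames(num)), , drop = FALSE]
    genes <- unique(genes)
  }
  rownames(num) <- genes
  expr_matrix(num, state = state)
}

#' Write an expression matrix as TSV with a YAML sidecar
#'
#' The sidecar (`<path>.yml`) records the normalization state so a
#' re-read can restore it; round-trips preserve values to near machine
#' precision.
#'
#' @param m An [expr_matrix()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(state = expr_state(m),
                        n_genes = nrow(m), n_samples = ncol(m)),
                   paste0(path, ".yml"))
  invisible(path)
}

.role_vocabulary <- c("primary", "metastatic", "normal")

#' Read a sample annotation table
#'
#' Required columns: `sample_id`, `role` (primary/metastatic/normal,
#' case-insensitive). Optional: `patient_id`, `cancer_type`,
#' `origin_tissue`, `target_tissues` (semicolon-delimited), `purity` in
#' \[0, 1\].
#'
#' @param path Path to a TSV file.
#' @return A data frame with `target_tissues` parsed into a list column.
#' @export
read_sample_annotation <- function(path) {
  if (!file.exists(path)) stop("cannot read sample annotation: ", path)
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c("sample_id", "role")) {
    if (!col %in% colnames(ann)) stop("annotation is missing required column '", col, "'")
  }
  ann$role <- tolower(trimws(ann$role))
  bad <- setdiff(unique(ann$role), .role_vocabulary)
  if (length(bad)) {
    stop("role values outside {primary, metastatic, normal}: ",
         paste(bad, collapse = ", "))
  }
  if (!"patient_id" %in% colnames(ann)) ann$patient_id <- NA_character_
  if (!"cancer_type" %in% colnames(ann)) ann$cancer_type <- NA_character_
  if (!"origin_tissue" %in% colnames(ann)) ann$origin_tissue <- NA_character_
  tt_raw <- if ("target_tissues" %in% colnames(ann)) {
    as.character(ann$target_tissues)
  } else {
    rep("", nrow(ann))
  }
  tt_raw[is.na(tt_raw)] <- ""
  ann$target_tissues <- I(lapply(strsplit(tt_raw, ";", fixed = TRUE),
                                 function(x) trimws(x[nzchar(trimws(x))])))
  if ("purity" %in% colnames(ann)) {
    ann$purity <- as.numeric(ann$purity)
    out_of_range <- !is.na(ann$purity) & (ann$purity < 0 | ann$purity > 1)
    if (any(out_of_range)) {
      stop("purity outside [0, 1] for sample(s): ",
           paste(ann$sample_id[out_of_range], collapse = ", "))
    }
  } else {
    ann$purity <- NA_real_
  }
  ann
}

#' Write a sample annotation table (list column collapsed with ';')
#'
#' @param ann Annotation data frame as returned by [read_sample_annotation()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  out <- ann
  out$target_tissues <- vapply(ann$target_tissues, paste, "", collapse = ";")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard MSigDB-style lines: set name, description, then gene symbols.
#' Duplicate genes within a set are dropped keeping the first occurrence;
#' duplicate set names are an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(stats::setNames(list(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3
  if (any(short)) {
    stop("GMT line with fewer than 3 fields (line ", which(short)[1], ") in ", path)
  }
  nm <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  stats::setNames(sets, nm)
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written for each set.
#' @return `path`, invisibly.
#' @export
write_gene_sets_gmt <- function(sets, path, description = "na") {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description, sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Normalize a counts matrix
#'
#' `cpm` scales each sample to counts per million. `uq` divides each
#' sample by its 75th percentile (type-7 linear-interpolation quantile).
#' `tmm_cpm` computes CPM on trimmed-mean-of-M-values effective library
#' sizes via edgeR, the standard implementation of the published TMM
#' procedure.
#'
#' @param m An [expr_matrix()] with `state = "counts"`.
#' @param method One of `"cpm"`, `"tmm_cpm"`, `"uq"`.
#' @return An [expr_matrix()] with the corresponding state.
#' @export
normalize_counts <- function(m, method = c("cpm", "tmm_cpm", "uq")) {
  method <- match.arg(method)
  if (expr_state(m) != "counts") {
    stop("normalize_counts expects state = 'counts', got '", expr_state(m), "'")
  }
  vals <- unclass(m)[, , drop = FALSE]
  lib <- colSums(vals)
  if (any(lib <= 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(vals)[lib <= 0], collapse = ", "))
  }
  out <- switch(method,
    cpm = sweep(vals, 2, lib / 1e6, "/"),
    uq = {
      q75 <- apply(vals, 2, stats::quantile, probs = 0.75, names = FALSE)
      if (any(q75 <= 0)) {
        stop("zero 75th percentile for sample(s): ",
             paste(colnames(vals)[q75 <= 0], collapse = ", "))
      }
      sweep(vals, 2, q75, "/")
    },
    tmm_cpm = {
      dge <- edgeR::calcNormFactors(edgeR::DGEList(counts = vals), method = "TMM")
      edgeR::cpm(dge, normalized.lib.sizes = TRUE)
    }
  )
  expr_matrix(out, state = method)
}

#' Restrict matrices to their common genes
#'
#' All matrices are cut down to the sorted intersection of their gene
#' lists, in identical order. Idempotent; an empty intersection is an
#' error.
#'
#' @param matrices List of [expr_matrix()] objects (length >= 2).
#' @return List of matrices over the shared, sorted gene list.
#' @export
harmonize_genes <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2) {
    stop("harmonize_genes needs a list of >= 2 matrices")
  }
  common <- Reduce(intersect, lapply(matrices, rownames))
  if (!length(common)) stop("empty gene intersection across matrices")
  common <- sort(common)
  lapply(matrices, function(m) m[common, , drop = FALSE])
}

#' Build a per-gene central reference profile for one tissue
#'
#' The per-gene median (bulk convention) or mean (single-cell convention,
#' where sparsity makes medians collapse) across the tissue's samples, on
#' the matrix's current state.
#'
#' @param m An [expr_matrix()].
#' @param tissue_samples Sample ids belonging to the tissue.
#' @param statistic `"median"` or `"mean"`.
#' @param tissue Tissue name recorded on the profile.
#' @return Named numeric vector of class `reference_profile` with
#'   `tissue`, `statistic` and `state` attributes.
#' @export
build_reference_profile <- function(m, tissue_samples,
                                    statistic = c("median", "mean"),
                                    tissue = NA_character_) {
  statistic <- match.arg(statistic)
  if (!length(tissue_samples)) stop("empty sample list for reference profile")
  missing_ids <- setdiff(tissue_samples, colnames(m))
  if (length(missing_ids)) {
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  }
  sub <- unclass(m)[, tissue_samples, drop = FALSE]
  vals <- if (statistic == "median") {
    apply(sub, 1, stats::median)
  } else {
    rowMeans(sub)
  }
  structure(stats::setNames(vals, rownames(m)),
            class = "reference_profile",
            tissue = tissue, statistic = statistic, state = expr_state(m))
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("reference_profile: tissue = %s, %d genes, statistic = %s\n",
              attr(x, "tissue"), length(x), attr(x, "statistic")))
  invisible(x)
}

#' Select the most variable genes across pooled matrices
#'
#' Variance is computed per gene on pooled log2(x + 1) values across all
#' samples of all supplied matrices (values taken as-is for log-space
#' input). Ties at the cutoff are broken toward the lexicographically
#' smaller gene symbol.
#'
#' @param matrices List of harmonized [expr_matrix()] objects.
#' @param k Number of genes to keep.
#' @return Character vector of gene symbols (length `min(k, n_genes)`),
#'   ordered by decreasing variance.
#' @export
select_variable_genes <- function(matrices, k) {
  if (!is.list(matrices)) matrices <- list(matrices)
  if (length(k) != 1 || !is.finite(k) || k <= 0) stop("k must be a positive integer")
  genes <- rownames(matrices[[1]])
  for (m in matrices[-1]) {
    if (!identical(rownames(m), genes)) {
      stop("matrices must be harmonized before selecting variable genes")
    }
  }
  pooled <- do.call(cbind, lapply(matrices, function(m) {
    v <- unclass(m)[, , drop = FALSE]
    if (expr_state(m) == "log_space") v else log2(v + 1)
  }))
  n <- ncol(pooled)
  if (n < 2) stop("need >= 2 pooled samples to compute variance")
  mu <- rowMeans(pooled)
  v <- rowSums((pooled - mu)^2) / (n - 1)
  ord <- order(-v, genes)
  genes[ord][seq_len(min(k, length(genes)))]
}

#' Expand multi-target samples into one pseudo-sample per target tissue
#'
#' A sample annotated with several target tissues is replaced by one
#' record per target tissue, keeping the expression linkage through
#' `source_sample_id`. Pseudo-sample ids are `original_id::TT`,
#' deterministic and reversible.
#'
#' @param ann Annotation data frame.
#' @return Expanded annotation with a `source_sample_id` column.
#' @export
expand_pseudo_samples <- function(ann) {
  n_tt <- lengths(ann$target_tissues)
  tumor_no_tt <- ann$role %in% c("primary", "metastatic") & n_tt == 0
  if (any(tumor_no_tt)) {
    warning(sum(tumor_no_tt), " tumor sample(s) with no target tissue pass through unchanged")
  }
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    tts <- ann$target_tissues[[i]]
    if (length(tts) <= 1) {
      row <- ann[i, , drop = FALSE]
      row$source_sample_id <- ann$sample_id[i]
      return(row)
    }
    out <- ann[rep(i, length(tts)), , drop = FALSE]
    out$sample_id <- paste0(ann$sample_id[i], "::", tts)
    out$source_sample_id <- ann$sample_id[i]
    out$target_tissues <- I(as.list(tts))
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
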
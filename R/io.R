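# Tabular input/output for the three study tables.
#
# Matrices are plain numeric matrices with samples in rows (rownames are
# sample identifiers, colnames are probe or gene identifiers). On disk the
# TCGA level-3 convention is features-in-rows; the `orientation` flag is
# explicit — no auto-detection — so parsing is deterministic.

read_matrix_tsv <- function(path, orientation) {
  if (!is.character(path) || length(path) != 1L) {
    stop_cgp("`path` must be a single file path")
  }
  if (!file.exists(path)) stop_cgp("file not found: %s", path)
  if (file.info(path)$size == 0) stop_cgp("parse error in %s: file is empty", path)
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                      stringsAsFactors = FALSE, colClasses = "character",
                      na.strings = c("NA", "NaN", "")),
    error = function(e) {
      stop_cgp("parse error in %s: %s", path, conditionMessage(e))
    })
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_cgp("parse error in %s: need an id column plus >= 1 data column and >= 1 data row", path)
  }
  row_ids <- df[[1L]]
  col_ids <- colnames(df)[-1L]
  raw <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop_cgp("parse error in %s: non-numeric value '%s' at row '%s', column '%s'",
             path, raw[b[1L], b[2L]], row_ids[b[1L]], col_ids[b[2L]])
  }
  dimnames(num) <- list(row_ids, col_ids)
  if (orientation == "features_in_rows") num <- t(num) # -> samples x features
  num
}

check_unique_ids <- function(m, path) {
  if (anyDuplicated(rownames(m))) {
    stop_cgp("duplicate sample id '%s' in %s",
             rownames(m)[duplicated(rownames(m))][1L], path)
  }
  if (anyDuplicated(colnames(m))) {
    stop_cgp("duplicate feature id '%s' in %s",
             colnames(m)[duplicated(colnames(m))][1L], path)
  }
  invisible(m)
}

#' Read a methylation beta-value matrix from TSV
#'
#' Parses a tab-separated matrix of methylation beta values (methylated
#' signal fraction, bounded in \[0,1\]) with one header row and one
#' identifier column, and validates it: every non-missing value must lie in
#' \[0,1\] and sample/feature identifiers must be unique. Missing cells
#' (empty, `NA`, `NaN`) are kept as `NA`; see [impute_missing()] before
#' clustering.
#'
#' @param path path to a TSV file.
#' @param orientation `"features_in_rows"` (TCGA level-3 convention, the
#'   default: rows are probes/genes, columns are samples) or
#'   `"samples_in_rows"`.
#' @return a numeric matrix, samples in rows, features in columns.
#' @seealso [read_expression_matrix()], [aggregate_probes_to_genes()]
#' @export
read_beta_matrix <- function(path,
                             orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- read_matrix_tsv(path, orientation)
  check_unique_ids(m, path)
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    b <- bad[1L, ]
    stop_cgp("beta value out of [0, 1] in %s: %g at sample '%s', feature '%s'",
             path, m[b[1L], b[2L]], rownames(m)[b[1L]], colnames(m)[b[2L]])
  }
  m
}

collapse_columns_mean <- function(m) {
  groups <- colnames(m)
  keep <- unique(groups)
  idx <- split(seq_along(groups), factor(groups, levels = keep))
  out <- vapply(idx, function(j) rowMeans(m[, j, drop = FALSE], na.rm = TRUE),
                numeric(nrow(m)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), keep))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(m)
  out
}

#' Read a gene expression matrix from TSV
#'
#' Like [read_beta_matrix()] but without the \[0,1\] range check. Rows
#' sharing a gene symbol are collapsed to their per-sample mean (the count
#' of collapsed rows is logged); expression values are assumed to be on a
#' log-like scale, which is the caller's responsibility.
#'
#' @inheritParams read_beta_matrix
#' @return a numeric matrix, samples in rows, unique gene symbols in columns.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("features_in_rows", "samples_in_rows")) {
  orientation <- match.arg(orientation)
  m <- read_matrix_tsv(path, orientation)
  if (anyDuplicated(rownames(m))) {
    stop_cgp("duplicate sample id '%s' in %s",
             rownames(m)[duplicated(rownames(m))][1L], path)
  }
  ndup <- sum(duplicated(colnames(m)))
  if (ndup > 0L) {
    m <- collapse_columns_mean(m)
    cgp_log("collapsed %d duplicate gene-symbol row(s) by per-sample mean", ndup)
  }
  m
}

#' Read a clinical table with survival outcome from TSV
#'
#' Requires a sample identifier, survival time in months, and a binary
#' event indicator (1 = death observed, 0 = censored). Rows with missing
#' survival or event are dropped, with the drop count logged.
#'
#' @param path path to a TSV file with a header.
#' @param id_col,time_col,event_col column names holding the sample id,
#'   survival months and event flag.
#' @return a `data.frame` with columns `sample_id`, `survival_months`,
#'   `event`; any further columns (e.g. age, sex) are carried along.
#' @export
read_clinical <- function(path, id_col = "sample_id",
                          time_col = "survival_months", event_col = "event") {
  if (!file.exists(path)) stop_cgp("file not found: %s", path)
  if (file.info(path)$size == 0) stop_cgp("parse error in %s: file is empty", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(id_col, time_col, event_col), colnames(df))
  if (length(missing_cols) > 0L) {
    stop_cgp("clinical table %s lacks required column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  }
  names(df)[match(c(id_col, time_col, event_col), names(df))] <-
    c("sample_id", "survival_months", "event")
  n0 <- nrow(df)
  df <- df[!is.na(df$survival_months) & !is.na(df$event), , drop = FALSE]
  if (nrow(df) < n0) {
    cgp_log("dropped %d clinical record(s) with missing survival or event", n0 - nrow(df))
  }
  if (nrow(df) == 0L) stop_cgp("clinical table %s has no complete records", path)
  if (!is_binary01(df$event)) {
    stop_cgp("event column in %s must be 0/1; found value '%s'",
             path, df$event[!df$event %in% c(0, 1)][1L])
  }
  if (any(df$survival_months < 0)) {
    stop_cgp("negative survival time in %s for sample '%s'",
             path, df$sample_id[df$survival_months < 0][1L])
  }
  if (anyDuplicated(df$sample_id)) {
    stop_cgp("duplicate sample id '%s' in %s",
             df$sample_id[duplicated(df$sample_id)][1L], path)
  }
  df$sample_id <- as.character(df$sample_id)
  df$event <- as.integer(df$event)
  rownames(df) <- NULL
  df
}

#' Read a two-column probe-to-gene map from TSV
#'
#' @param path TSV with a header and (at least) two columns; the first two
#'   are taken as probe id and gene symbol.
#' @return a `data.frame` with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  if (!file.exists(path)) stop_cgp("file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_cgp("probe map %s needs two columns", path)
  out <- data.frame(probe_id = as.character(df[[1L]]),
                    gene_symbol = as.character(df[[2L]]),
                    stringsAsFactors = FALSE)
  out[!is.na(out$probe_id) & !is.na(out$gene_symbol), , drop = FALSE]
}

#' Read a gene panel (one symbol per line)
#'
#' @param path text file, one gene symbol per line; blank lines ignored.
#' @return a character vector of unique symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop_cgp("file not found: %s", path)
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (length(x) == 0L) stop_cgp("gene list %s is empty", path)
  unique(x)
}

#' Aggregate probe-level beta values to gene level
#'
#' Each gene's value per sample is the unweighted mean of its mapped probes'
#' non-missing values; a gene whose probes are all missing for a sample is
#' missing for that sample. Probes absent from the map are dropped (count
#' logged). A probe may map to several genes and several probes to one gene.
#'
#' @param beta samples-by-probes matrix from [read_beta_matrix()].
#' @param map `data.frame` from [read_probe_map()].
#' @return samples-by-genes matrix; gene order follows first appearance in
#'   the map.
#' @export
aggregate_probes_to_genes <- function(beta, map) {
  if (!all(c("probe_id", "gene_symbol") %in% colnames(map))) {
    stop_cgp("probe map must have columns probe_id and gene_symbol")
  }
  present <- map$probe_id %in% colnames(beta)
  if (!any(present)) stop_cgp("no beta feature appears in the probe map")
  n_unmapped <- sum(!colnames(beta) %in% map$probe_id)
  if (n_unmapped > 0L) cgp_log("dropped %d unmapped probe(s)", n_unmapped)
  map <- map[present, , drop = FALSE]
  genes <- unique(map$gene_symbol)
  idx <- split(match(map$probe_id, colnames(beta)),
               factor(map$gene_symbol, levels = genes))
  out <- vapply(idx, function(j) rowMeans(beta[, j, drop = FALSE], na.rm = TRUE),
                numeric(nrow(beta)))
  if (is.null(dim(out))) out <- matrix(out, nrow = nrow(beta), dimnames = list(rownames(beta), genes))
  out[is.nan(out)] <- NA_real_
  rownames(out) <- rownames(beta)
  out
}

#' Restrict a matrix to a gene panel
#'
#' Keeps the intersection of the matrix features and the panel, preserving
#' the matrix's feature order; the intersection size is logged.
#'
#' @param m samples-by-features numeric matrix.
#' @param panel character vector of gene symbols.
#' @return the column-restricted matrix.
#' @export
restrict_to_panel <- function(m, panel) {
  if (length(panel) == 0L) stop_cgp("gene panel is empty")
  keep <- colnames(m) %in% panel
  if (!any(keep)) stop_cgp("gene panel shares no features with the matrix")
  cgp_log("panel restriction kept %d of %d features", sum(keep), ncol(m))
  m[, keep, drop = FALSE]
}

#' Restrict all three study tables to their shared samples
#'
#' Samples are intersected across the beta matrix, the expression matrix and
#' the clinical table, and all three are returned in one canonical
#' (lexicographic) sample order. Per-input drop counts are logged.
#'
#' @param beta,expression samples-by-features matrices.
#' @param clinical `data.frame` from [read_clinical()].
#' @return a list with elements `beta`, `expression`, `clinical`.
#' @export
align_samples <- function(beta, expression, clinical) {
  shared <- sort(Reduce(intersect,
                        list(rownames(beta), rownames(expression), clinical$sample_id)))
  if (length(shared) < 2L) {
    stop_cgp("fewer than 2 samples shared among beta, expression and clinical inputs")
  }
  for (nm in c("beta", "expression", "clinical")) {
    n_in <- switch(nm, beta = nrow(beta), expression = nrow(expression),
                   clinical = nrow(clinical))
    if (n_in > length(shared)) {
      cgp_log("align_samples dropped %d sample(s) from %s", n_in - length(shared), nm)
    }
  }
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  rownames(clin) <- NULL
  list(beta = beta[shared, , drop = FALSE],
       expression = expression[shared, , drop = FALSE],
       clinical = clin)
}

#' Drop high-missingness features and median-impute the rest
#'
#' Features missing in more than `max_missing_frac` of samples are removed
#' (count logged); remaining missing values are replaced with the
#' per-feature median, which keeps beta values inside \[0,1\].
#'
#' @param m samples-by-features numeric matrix.
#' @param max_missing_frac maximum tolerated fraction of missing values per
#'   feature (default 0.2).
#' @return the matrix with no missing values.
#' @export
impute_missing <- function(m, max_missing_frac = 0.2) {
  miss_frac <- colMeans(is.na(m))
  drop <- miss_frac > max_missing_frac
  if (all(drop)) stop_cgp("every feature exceeds the missingness threshold")
  if (any(drop)) {
    cgp_log("dropped %d feature(s) with > %.0f%% missing values",
            sum(drop), 100 * max_missing_frac)
    m <- m[, !drop, drop = FALSE]
  }
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) > 0L) {
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    m[nas] <- med[nas[, 2L]]
  }
  m
}

#' Write a samples-by-features matrix to TSV
#'
#' Inverse of [read_beta_matrix()] / [read_expression_matrix()]: values
#' round-trip to within text-representation precision.
#'
#' @param m samples-by-features numeric matrix.
#' @param path output file path.
#' @param orientation on-disk orientation, as in [read_beta_matrix()].
#' @param id_label header of the identifier column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path,
                             orientation = c("features_in_rows", "samples_in_rows"),
                             id_label = "id") {
  orientation <- match.arg(orientation)
  out <- if (orientation == "features_in_rows") t(m) else m
  df <- data.frame(rownames(out), out, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_label, colnames(out))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data frame to TSV
#'
#' @param df a `data.frame` (clinical table, panel, per-iteration results...).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
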
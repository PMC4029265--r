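# Marker panel extraction: genes whose between-phenotype methylation and
# expression differences are concordant — hypermethylated AND down-regulated
# in the CIMP-positive phenotype (hyper_down), or hypomethylated AND
# up-regulated (hypo_up). Deltas are positive-phenotype minus
# negative-phenotype throughout.

#' Join methylation and expression cluster means by gene symbol
#'
#' Inner join of two [cluster_means()] tables on gene symbol; the join size
#' is logged. Adds the between-phenotype deltas
#' (`delta_beta`, `delta_expr` = mean in positive minus mean in negative).
#'
#' @param meth_means,expr_means `data.frame`s with columns `gene`,
#'   `mean_positive`, `mean_negative` (from [cluster_means()]).
#' @return `data.frame` over shared genes with the four means and both deltas.
#' @export
link_by_gene <- function(meth_means, expr_means) {
  for (df in list(meth_means, expr_means)) {
    if (!all(c("gene", "mean_positive", "mean_negative") %in% colnames(df))) {
      stop_cgp("cluster-mean tables need columns gene, mean_positive, mean_negative")
    }
  }
  shared <- intersect(meth_means$gene, expr_means$gene)
  if (length(shared) == 0L) stop_cgp("no genes shared between methylation and expression tables")
  cgp_log("linked %d gene(s) by symbol", length(shared))
  mm <- meth_means[match(shared, meth_means$gene), , drop = FALSE]
  em <- expr_means[match(shared, expr_means$gene), , drop = FALSE]
  data.frame(gene = shared,
             beta_positive = mm$mean_positive,
             beta_negative = mm$mean_negative,
             expr_positive = em$mean_positive,
             expr_negative = em$mean_negative,
             delta_beta = mm$mean_positive - mm$mean_negative,
             delta_expr = em$mean_positive - em$mean_negative,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Filter concordant methylation-expression markers
#'
#' Selects genes passing the direction-specific effect-size inequalities:
#' `hyper_down` requires `delta_beta >= delta_beta_min` and
#' `delta_expr <= -delta_expr_min`; `hypo_up` requires
#' `delta_beta <= -delta_beta_min` and `delta_expr >= delta_expr_min`.
#' With both thresholds zero this is a strict sign-concordance screen; a
#' gene satisfying both direction rules simultaneously (both deltas tied at
#' zero) is excluded. The panel is ordered by `|delta_beta|` descending.
#' An empty panel is a valid result and only triggers a logged warning.
#'
#' @param joined output of [link_by_gene()].
#' @param direction `"both"` (default), `"hyper_down"` or `"hypo_up"`.
#' @param delta_beta_min minimum absolute beta difference (default 0.1, a
#'   conventional methylation effect floor).
#' @param delta_expr_min minimum absolute expression difference (default 0:
#'   sign concordance only).
#' @return a `cgp_panel` data frame with columns `gene`, `direction`,
#'   `delta_beta`, `delta_expr`; the thresholds used are kept as attributes.
#' @export
filter_markers <- function(joined, direction = c("both", "hyper_down", "hypo_up"),
                           delta_beta_min = 0.1, delta_expr_min = 0) {
  direction <- match.arg(direction)
  if (nrow(joined) == 0L) stop_cgp("joined table is empty")
  if (delta_beta_min < 0 || delta_expr_min < 0) stop_cgp("thresholds must be >= 0")
  hyper <- joined$delta_beta >= delta_beta_min & joined$delta_expr <= -delta_expr_min
  hypo <- joined$delta_beta <= -delta_beta_min & joined$delta_expr >= delta_expr_min
  tied <- hyper & hypo
  dir_vec <- rep(NA_character_, nrow(joined))
  dir_vec[hyper & !tied] <- "hyper_down"
  dir_vec[hypo & !tied] <- "hypo_up"
  keep <- if (direction == "both") !is.na(dir_vec) else !is.na(dir_vec) & dir_vec == direction
  panel <- data.frame(gene = joined$gene[keep],
                      direction = dir_vec[keep],
                      delta_beta = joined$delta_beta[keep],
                      delta_expr = joined$delta_expr[keep],
                      row.names = NULL, stringsAsFactors = FALSE)
  panel <- panel[order(-abs(panel$delta_beta), panel$gene), , drop = FALSE]
  rownames(panel) <- NULL
  if (nrow(panel) == 0L) cgp_log("warning: marker filter returned an empty panel")
  structure(panel,
            delta_beta_min = delta_beta_min,
            delta_expr_min = delta_expr_min,
            direction = direction,
            class = c("cgp_panel", "data.frame"))
}

#' @export
print.cgp_panel <- function(x, ...) {
  cat(sprintf("predictor panel: %d gene(s) [delta_beta_min = %g, delta_expr_min = %g, direction = %s]\n",
              nrow(x), attr(x, "delta_beta_min"), attr(x, "delta_expr_min"),
              attr(x, "direction")))
  print.data.frame(x, ...)
  invisible(x)
}
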
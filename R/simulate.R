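# Synthetic paired methylation/expression/clinical cohorts with planted
# CIMP structure and known truth, so every pipeline stage is testable
# without external data.
#
# Methylation is Beta-distributed per gene with a shared precision
# parameter (the simplest generator respecting the [0,1] support);
# marker-gene means are shifted upward in the positive phenotype and
# marker-gene expression is shifted downward (hypermethylated AND
# down-regulated, the concordance the filter looks for). Survival is
# exponential with the positive-phenotype hazard multiplied by the target
# hazard ratio; censoring is administrative-uniform (non-informative).

#' Simulate a paired methylation / expression / survival cohort
#'
#' Background genes share a Beta-distributed methylation mean (uniform in
#' \[0.1, 0.6\]) across phenotypes; the `n_markers` planted marker genes
#' have their mean shifted by `+delta_beta` in the CIMP-positive phenotype
#' (clipped to \[0.02, 0.98\]) and their expression lowered by `delta_expr`
#' units there. Optional discordant decoys are hypermethylated but
#' *up*-regulated, to exercise rejection by the concordance filter.
#' Survival times are exponential with mean `baseline_scale_months` in the
#' negative phenotype and hazard multiplied by `hazard_ratio` in the
#' positive one; independent uniform censoring is calibrated so the
#' expected censored fraction is `censoring_rate`.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param n_markers number of planted concordant marker genes.
#' @param frac_positive expected fraction of CIMP-positive samples.
#' @param delta_beta planted between-phenotype beta difference on markers.
#' @param delta_expr planted expression decrease (positive number of
#'   intensity units) of markers in the positive phenotype.
#' @param base_beta_dispersion Beta-distribution precision (shape1 + shape2);
#'   larger = tighter beta values around the gene mean.
#' @param hazard_ratio true hazard ratio of positive vs negative phenotype.
#' @param baseline_scale_months mean survival (months) in the negative
#'   phenotype.
#' @param censoring_rate expected fraction of censored subjects, in \[0, 1).
#' @param n_discordant number of hypermethylated-but-up-regulated decoy
#'   genes (default 0).
#' @param seed integer seed; a fixed seed gives byte-identical cohorts.
#' @return a `cgp_cohort` list with `beta` and `expression`
#'   (samples-by-genes matrices), `clinical` (`sample_id`,
#'   `survival_months`, `event`), and `truth` (planted labels, marker table
#'   with signed per-gene deltas, discordant genes, generator parameters).
#' @export
simulate_cohort <- function(n_samples = 200L, n_genes = 500L, n_markers = 30L,
                            frac_positive = 0.3, delta_beta = 0.3, delta_expr = 2,
                            base_beta_dispersion = 50, hazard_ratio = 2,
                            baseline_scale_months = 60, censoring_rate = 0.2,
                            n_discordant = 0L, seed = 1L) {
  if (n_samples < 4L) stop_cgp("n_samples must be >= 4")
  if (n_markers + n_discordant > n_genes) stop_cgp("n_markers + n_discordant exceeds n_genes")
  if (frac_positive <= 0 || frac_positive >= 1) stop_cgp("frac_positive must be in (0, 1)")
  if (censoring_rate < 0 || censoring_rate >= 1) stop_cgp("censoring_rate must be in [0, 1)")
  if (hazard_ratio <= 0 || baseline_scale_months <= 0 || base_beta_dispersion <= 0) {
    stop_cgp("hazard_ratio, baseline_scale_months and base_beta_dispersion must be > 0")
  }
  if (delta_beta < 0 || delta_beta > 0.9) stop_cgp("delta_beta must be in [0, 0.9]")
  sample_ids <- sprintf("S%04d", seq_len(n_samples))
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  withr::with_seed(as.integer(seed), {
    n_pos <- max(1L, min(n_samples - 1L, round(frac_positive * n_samples)))
    pos_idx <- sample.int(n_samples, n_pos)
    is_pos <- seq_len(n_samples) %in% pos_idx
    shifted <- sample(gene_ids, n_markers + n_discordant)
    markers <- shifted[seq_len(n_markers)]
    discordant <- if (n_discordant > 0L) shifted[n_markers + seq_len(n_discordant)] else character(0)

    mu_bg <- stats::runif(n_genes, 0.1, 0.6)
    names(mu_bg) <- gene_ids
    mu_pos <- mu_bg
    mu_pos[shifted] <- pmin(pmax(mu_bg[shifted] + delta_beta, 0.02), 0.98)
    mu_mat <- matrix(rep(mu_bg, each = n_samples), nrow = n_samples)
    mu_mat[is_pos, ] <- matrix(rep(mu_pos, each = n_pos), nrow = n_pos)
    phi <- base_beta_dispersion
    beta <- matrix(stats::rbeta(n_samples * n_genes, c(mu_mat) * phi,
                                (1 - c(mu_mat)) * phi),
                   nrow = n_samples, dimnames = list(sample_ids, gene_ids))
    beta <- pmin(pmax(beta, 0), 1)

    expr_base <- stats::rnorm(n_genes, mean = 8, sd = 1.5)
    names(expr_base) <- gene_ids
    expression <- matrix(rep(expr_base, each = n_samples), nrow = n_samples,
                         dimnames = list(sample_ids, gene_ids)) +
      matrix(stats::rnorm(n_samples * n_genes, sd = 1), nrow = n_samples)
    expression[is_pos, markers] <- expression[is_pos, markers] - delta_expr
    if (n_discordant > 0L) {
      expression[is_pos, discordant] <- expression[is_pos, discordant] + delta_expr
    }

    rate <- (1 / baseline_scale_months) * ifelse(is_pos, hazard_ratio, 1)
    t_event <- stats::rexp(n_samples, rate)
    if (censoring_rate > 0) {
      cens_frac <- function(m) {
        mean((1 - exp(-rate * m)) / (rate * m)) - censoring_rate
      }
      m_max <- stats::uniroot(cens_frac, interval = c(1e-6, 1e7), tol = 1e-8)$root
      t_cens <- stats::runif(n_samples, 0, m_max)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n_samples)
    }
  })
  truth <- list(
    planted_labels = stats::setNames(
      ifelse(is_pos, "CIMP_positive", "CIMP_negative"), sample_ids),
    marker_genes = data.frame(
      gene = markers,
      delta_beta = unname(mu_pos[markers] - mu_bg[markers]),
      delta_expr = rep(-delta_expr, n_markers),
      stringsAsFactors = FALSE),
    discordant_genes = discordant,
    hazard_ratio = hazard_ratio,
    censoring_rate = censoring_rate,
    params = list(n_samples = n_samples, n_genes = n_genes,
                  n_markers = n_markers, frac_positive = frac_positive,
                  delta_beta = delta_beta, delta_expr = delta_expr,
                  base_beta_dispersion = base_beta_dispersion,
                  hazard_ratio = hazard_ratio,
                  baseline_scale_months = baseline_scale_months,
                  censoring_rate = censoring_rate,
                  n_discordant = n_discordant, seed = as.integer(seed)))
  structure(list(beta = beta, expression = expression,
                 clinical = data.frame(sample_id = sample_ids,
                                       survival_months = time,
                                       event = event,
                                       stringsAsFactors = FALSE),
                 truth = truth),
            class = "cgp_cohort")
}

#' Write a simulated cohort to a directory of TSV files
#'
#' Emits `beta.tsv`, `expression.tsv` (features-in-rows), `clinical.tsv`,
#' `truth_markers.tsv` and `truth_labels.tsv` in the dialects read by the
#' input functions; read-back round-trips to text precision.
#'
#' @param cohort a `cgp_cohort` from [simulate_cohort()].
#' @param directory output directory (created if absent).
#' @return named character vector of the files written, invisibly.
#' @export
write_cohort <- function(cohort, directory) {
  if (!inherits(cohort, "cgp_cohort")) stop_cgp("not a cgp_cohort")
  if (!is.character(directory) || length(directory) != 1L || !nzchar(directory)) {
    stop_cgp("directory must be a non-empty path")
  }
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_cgp("cannot create directory %s", directory)
  }
  paths <- c(beta = file.path(directory, "beta.tsv"),
             expression = file.path(directory, "expression.tsv"),
             clinical = file.path(directory, "clinical.tsv"),
             truth_markers = file.path(directory, "truth_markers.tsv"),
             truth_labels = file.path(directory, "truth_labels.tsv"))
  write_matrix_tsv(cohort$beta, paths["beta"], id_label = "gene")
  write_matrix_tsv(cohort$expression, paths["expression"], id_label = "gene")
  write_table_tsv(cohort$clinical, paths["clinical"])
  write_table_tsv(cohort$truth$marker_genes, paths["truth_markers"])
  write_table_tsv(data.frame(sample_id = names(cohort$truth$planted_labels),
                             phenotype = unname(cohort$truth$planted_labels),
                             stringsAsFactors = FALSE),
                  paths["truth_labels"])
  invisible(paths)
}

#' @export
print.cgp_cohort <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "synthetic cohort: %d samples x %d genes, %d planted marker(s), HR = %g, censoring = %g\n",
    p$n_samples, p$n_genes, p$n_markers, p$hazard_ratio, p$censoring_rate))
  print(table(phenotype = x$truth$planted_labels))
  invisible(x)
}
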
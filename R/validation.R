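# Resampling validation of a clustering and its marker panel:
# (1) bootstrap cluster stability — resample patients with replacement,
#     re-cluster on the original clustering genes, and measure per-iteration
#     sensitivity (agreement with the original phenotype labels after
#     optimal label alignment);
# (2) random-gene-selection null — panels of the same size drawn uniformly
#     from the gene universe, re-clustered and survival-tested, giving an
#     empirical null for the observed panel's log-rank statistic.
# Both empirical p-values use add-one smoothing, so they are never zero:
# the smallest attainable value is 1 / (iterations + 1).

#' Bootstrap stability of the phenotype clustering
#'
#' Per iteration, `n` samples are drawn with replacement, the resampled
#' beta matrix restricted to the original clustering features is
#' re-clustered with k = 2, bootstrap cluster labels are aligned to the
#' original phenotypes by the label permutation maximizing agreement, and
#' the sensitivity is the fraction of resampled draws whose bootstrap label
#' matches their original label (alignment guarantees sensitivity >= 0.5).
#' The empirical p-value is the add-one-smoothed fraction of iterations
#' with sensitivity at or below the chance level (the larger original
#' phenotype proportion).
#'
#' @param beta samples-by-features matrix with no missing values, covering
#'   the assignment's samples.
#' @param clustering_features features to re-cluster on (the original
#'   clustering genes); must be a subset of `colnames(beta)`.
#' @param original a labeled `cgp_assignment` for the same samples.
#' @param iterations number of bootstrap iterations (default 1000).
#' @param seed integer seed; the procedure is bit-reproducible given
#'   `(seed, iterations)`.
#' @param n_restarts k-means++ restarts per re-clustering (default 5; the
#'   resampled problems are small multiples of the original one).
#' @return a `cgp_bootstrap` list: per-iteration `sensitivities`,
#'   `mean_sensitivity`, `empirical_p`, `chance_level`, redraw count, seed.
#' @export
bootstrap_stability <- function(beta, clustering_features, original,
                                iterations = 1000L, seed = 1L, n_restarts = 5L) {
  if (iterations < 1L) stop_cgp("iterations must be >= 1")
  if (is.null(original$labels)) {
    stop_cgp("original assignment has no phenotype labels; run label_extreme_phenotypes()")
  }
  if (!all(clustering_features %in% colnames(beta))) {
    stop_cgp("clustering_features must be a subset of the beta features")
  }
  if (!setequal(rownames(beta), original$sample_ids)) {
    stop_cgp("beta samples must match the original assignment's samples")
  }
  sub <- beta[original$sample_ids, clustering_features, drop = FALSE]
  keep <- original$labels %in% c("CIMP_positive", "CIMP_negative")
  sub <- sub[keep, , drop = FALSE]
  orig_lab <- original$labels[keep]
  n <- nrow(sub)
  if (n < 2L) stop_cgp("need at least 2 labeled samples")
  chance <- max(mean(orig_lab == "CIMP_positive"), mean(orig_lab == "CIMP_negative"))
  sens <- numeric(iterations)
  redraws <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(iterations)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        Xi <- sub[idx, , drop = FALSE]
        if (length(unique(idx)) > 1L && sum(sweep(Xi, 2, Xi[1L, ], "-")^2) > 0) break
        redraws <- redraws + 1L
      }
      rownames(Xi) <- sprintf("bs%05d", seq_len(n))
      kseed <- sample.int(2147483646L, 1L)
      fit <- kmeans_cluster(Xi, k = 2L, seed = kseed, n_restarts = n_restarts)
      agree <- mean((fit$cluster == 1L) == (orig_lab[idx] == "CIMP_positive"))
      sens[b] <- max(agree, 1 - agree)
    }
  })
  if (redraws > 0L) cgp_log("re-drew %d degenerate bootstrap sample(s)", redraws)
  structure(list(iterations = as.integer(iterations),
                 sensitivities = sens,
                 mean_sensitivity = mean(sens),
                 empirical_p = (1 + sum(sens <= chance)) / (iterations + 1),
                 chance_level = chance,
                 redraws = redraws,
                 seed = as.integer(seed)),
            class = "cgp_bootstrap")
}

#' Random-gene-selection null for a marker panel
#'
#' Per iteration, `panel_size` genes are drawn uniformly without
#' replacement from the gene universe, samples are re-clustered on those
#' genes (k = 2, extreme-phenotype labeling) and the two groups are
#' compared with the log-rank test; the recorded chi-square values form the
#' null distribution. The empirical p-value is add-one smoothed:
#' `(1 + #\{null chi-square >= observed\}) / (iterations + 1)` (larger
#' chi-square = more extreme).
#'
#' @param beta samples-by-features matrix with no missing values.
#' @param clinical clinical table ([read_clinical()]) covering the beta
#'   samples.
#' @param panel_size number of genes per random panel (the size of the
#'   observed predictor panel).
#' @param gene_universe genes to draw from (default: all beta features).
#' @param iterations number of random panels (default 1000).
#' @param seed integer seed.
#' @param observed_statistic the log-rank chi-square of the real predictor's
#'   survival test.
#' @param n_restarts k-means++ restarts per re-clustering (default 5).
#' @return a `cgp_randomtest` list: `null_statistics`, `observed_statistic`,
#'   `empirical_p`, `panel_size`, seed.
#' @export
random_gene_test <- function(beta, clinical, panel_size,
                             gene_universe = colnames(beta),
                             iterations = 1000L, seed = 1L,
                             observed_statistic, n_restarts = 5L) {
  if (iterations < 1L) stop_cgp("iterations must be >= 1")
  if (!all(gene_universe %in% colnames(beta))) {
    stop_cgp("gene_universe must be a subset of the beta features")
  }
  if (panel_size < 1L || panel_size > length(gene_universe)) {
    stop_cgp("panel_size (%d) must be between 1 and the universe size (%d)",
             panel_size, length(gene_universe))
  }
  shared <- intersect(rownames(beta), clinical$sample_id)
  if (length(shared) < 2L) stop_cgp("fewer than 2 samples shared between beta and clinical")
  X <- beta[shared, , drop = FALSE]
  clin <- clinical[match(shared, clinical$sample_id), , drop = FALSE]
  null_stats <- numeric(iterations)
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(iterations)) {
      genes <- sample(gene_universe, panel_size)
      kseed <- sample.int(2147483646L, 1L)
      sub <- X[, genes, drop = FALSE]
      fit <- kmeans_cluster(sub, k = 2L, seed = kseed, n_restarts = n_restarts)
      fit <- label_extreme_phenotypes(fit, sub)
      null_stats[b] <- logrank_test(clin$survival_months, clin$event, fit$labels)$chi_square
    }
  })
  structure(list(iterations = as.integer(iterations),
                 null_statistics = null_stats,
                 observed_statistic = observed_statistic,
                 empirical_p = (1 + sum(null_stats >= observed_statistic)) /
                   (iterations + 1),
                 panel_size = as.integer(panel_size),
                 seed = as.integer(seed)),
            class = "cgp_randomtest")
}

#' @export
print.cgp_bootstrap <- function(x, ...) {
  cat(sprintf(
    "bootstrap stability: %d iteration(s), mean sensitivity = %.3f (chance level %.3f), empirical p = %.4g\n",
    x$iterations, x$mean_sensitivity, x$chance_level, x$empirical_p))
  invisible(x)
}

#' @export
print.cgp_randomtest <- function(x, ...) {
  cat(sprintf(
    "random-gene test: %d panel(s) of %d gene(s); observed chi-square = %.4g, empirical p = %.4g\n",
    x$iterations, x$panel_size, x$observed_statistic, x$empirical_p))
  invisible(x)
}
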
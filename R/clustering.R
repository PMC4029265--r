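# Phenotype discovery: Lloyd k-means with k-means++ seeding on the beta
# matrix, samples as observations, Euclidean distance on raw beta values
# (already bounded, so no feature scaling). The cluster with the highest
# centroid mean beta is the CIMP-positive (methylator) phenotype.

squared_dist_to_centers <- function(X, C) {
  d2 <- sweep(-2 * X %*% t(C), 2, rowSums(C^2), "+") + rowSums(X^2)
  pmax(d2, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2min <- rowSums(sweep(X, 2, X[centers[1L], ], "-")^2)
  for (j in seq_len(k)[-1L]) {
    centers[j] <- if (all(d2min <= 0)) sample.int(n, 1L) else sample.int(n, 1L, prob = d2min)
    d2min <- pmin(d2min, rowSums(sweep(X, 2, X[centers[j], ], "-")^2))
  }
  centers
}

lloyd_once <- function(X, k, max_iter = 300L) {
  n <- nrow(X)
  centers <- X[kmeanspp_init(X, k), , drop = FALSE]
  cl_prev <- integer(n)
  trace <- numeric(0)
  cl <- cl_prev
  wss <- NA_real_
  for (it in seq_len(max_iter)) {
    d2 <- squared_dist_to_centers(X, centers)
    cl <- max.col(-d2, ties.method = "first")
    empty <- which(tabulate(cl, k) == 0L)
    if (length(empty) > 0L) {
      # re-seed each empty cluster with the point farthest from its centroid
      pd <- d2[cbind(seq_len(n), cl)]
      for (j in empty) {
        far <- which.max(pd)
        cl[far] <- j
        pd[far] <- -Inf
      }
    }
    centers <- rowsum(X, cl) / tabulate(cl, k)
    wss <- sum((X - centers[cl, , drop = FALSE])^2)
    trace <- c(trace, wss)
    if (identical(cl, cl_prev)) break
    cl_prev <- cl
  }
  list(cluster = cl, centers = centers, tot_withinss = wss,
       wss_trace = trace, iterations = it)
}

#' Cluster samples by k-means on methylation beta values
#'
#' Runs Lloyd's algorithm with k-means++ initialization `n_restarts` times
#' and keeps the restart with the lowest within-cluster sum of squares.
#' Deterministic given `(seed, n_restarts)`. An empty cluster arising during
#' iteration is re-seeded with the point farthest from its current centroid.
#' Convergence: assignments unchanged, or 300 iterations.
#'
#' @param beta samples-by-features numeric matrix with no missing values
#'   (see [impute_missing()]).
#' @param k number of clusters (>= 2; default 2, the two CIMP phenotypes).
#' @param seed integer seed governing all restarts.
#' @param n_restarts number of k-means++ restarts (default 20).
#' @return an object of class `cgp_assignment`: sample ids, integer cluster
#'   per sample, centroids (k x features), total within-cluster sum of
#'   squares, the per-iteration WSS trace of the winning restart, the
#'   feature ids used, and the seed/restart count. Phenotype labels are
#'   attached by [label_extreme_phenotypes()].
#' @export
kmeans_cluster <- function(beta, k = 2L, seed = 1L, n_restarts = 20L) {
  if (!is.matrix(beta) || !is.numeric(beta)) stop_cgp("beta must be a numeric matrix")
  if (anyNA(beta)) stop_cgp("beta contains missing values; run impute_missing() first")
  n <- nrow(beta)
  k <- as.integer(k)
  if (k < 2L) stop_cgp("k must be >= 2")
  if (k > n) stop_cgp("k = %d exceeds the number of samples (%d)", k, n)
  if (n_restarts < 1L) stop_cgp("n_restarts must be >= 1")
  X <- unname(beta)
  if (sum(sweep(X, 2, X[1L, ], "-")^2) == 0) {
    stop_cgp("degenerate input: all samples are identical")
  }
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(n_restarts)) {
      fit <- lloyd_once(X, k)
      if (is.null(best) || fit$tot_withinss < best$tot_withinss) best <- fit
    }
  })
  centroids <- best$centers
  dimnames(centroids) <- list(paste0("cluster_", seq_len(k)), colnames(beta))
  structure(list(
    sample_ids = rownames(beta),
    cluster = best$cluster,
    labels = NULL,
    cluster_labels = NULL,
    centroids = centroids,
    within_cluster_ss = best$tot_withinss,
    wss_trace = best$wss_trace,
    clustering_features = colnames(beta),
    k = k,
    seed = as.integer(seed),
    n_restarts = as.integer(n_restarts),
    iterations = best$iterations
  ), class = "cgp_assignment")
}

#' Label the extreme phenotypes of a clustering
#'
#' The cluster whose centroid has the highest mean beta over the clustering
#' features is labeled `CIMP_positive` (the methylator phenotype), the
#' lowest `CIMP_negative`; for k > 2 the remaining clusters become
#' `intermediate_<i>` and are excluded from two-group analyses downstream.
#' On an exact tie of centroid means, the larger cluster is labeled
#' negative, with a warning.
#'
#' @param assignment a `cgp_assignment` from [kmeans_cluster()].
#' @param beta the matrix the assignment was produced from (used to check
#'   consistency of samples and features).
#' @return the assignment with per-sample `labels` and the per-cluster
#'   `cluster_labels` filled in.
#' @export
label_extreme_phenotypes <- function(assignment, beta) {
  if (!inherits(assignment, "cgp_assignment")) stop_cgp("not a cgp_assignment")
  if (!identical(rownames(beta), assignment$sample_ids) ||
      !identical(colnames(beta), assignment$clustering_features)) {
    stop_cgp("beta does not match the matrix the assignment was produced from")
  }
  k <- assignment$k
  cmeans <- rowMeans(assignment$centroids)
  sizes <- tabulate(assignment$cluster, k)
  lo <- which(cmeans == min(cmeans))
  hi <- which(cmeans == max(cmeans))
  if (min(cmeans) == max(cmeans)) {
    warning("centroid mean beta tie: labeling the larger cluster CIMP_negative",
            call. = FALSE)
    neg <- lo[which.max(sizes[lo])]
    hi <- setdiff(hi, neg)
    pos <- hi[which.min(sizes[hi])]
  } else {
    neg <- lo[which.max(sizes[lo])]
    if (length(lo) > 1L || length(hi) > 1L) {
      warning("centroid mean beta tie among clusters; broke by cluster size",
              call. = FALSE)
    }
    hi <- setdiff(hi, neg)
    pos <- hi[which.min(sizes[hi])]
  }
  cluster_labels <- paste0("intermediate_", seq_len(k))
  cluster_labels[neg] <- "CIMP_negative"
  cluster_labels[pos] <- "CIMP_positive"
  assignment$cluster_labels <- cluster_labels
  assignment$labels <- cluster_labels[assignment$cluster]
  assignment
}

#' Per-feature means within each labeled phenotype
#'
#' Arithmetic mean of every feature over the samples assigned to the
#' CIMP-positive and CIMP-negative phenotypes; intermediate clusters (k > 2)
#' are ignored. Works for both methylation and expression matrices.
#'
#' @param m samples-by-features numeric matrix whose samples are a subset of
#'   the assignment's samples.
#' @param assignment a labeled `cgp_assignment`
#'   (see [label_extreme_phenotypes()]).
#' @return `data.frame` with columns `gene`, `mean_positive`, `mean_negative`.
#' @export
cluster_means <- function(m, assignment) {
  if (is.null(assignment$labels)) {
    stop_cgp("assignment has no phenotype labels; run label_extreme_phenotypes() first")
  }
  if (!all(rownames(m) %in% assignment$sample_ids)) {
    stop_cgp("matrix contains samples absent from the assignment")
  }
  lab <- assignment$labels[match(rownames(m), assignment$sample_ids)]
  pos <- lab == "CIMP_positive"
  neg <- lab == "CIMP_negative"
  if (!any(pos) || !any(neg)) stop_cgp("a phenotype has no samples in the matrix")
  data.frame(gene = colnames(m),
             mean_positive = colMeans(m[pos, , drop = FALSE], na.rm = TRUE),
             mean_negative = colMeans(m[neg, , drop = FALSE], na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cgp_assignment <- function(x, ...) {
  cat(sprintf("k-means phenotype assignment: %d samples, k = %d, WSS = %.4g\n",
              length(x$sample_ids), x$k, x$within_cluster_ss))
  if (!is.null(x$labels)) {
    print(table(phenotype = x$labels))
  } else {
    print(table(cluster = x$cluster))
  }
  invisible(x)
}
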
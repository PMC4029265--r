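test_that("k = 2 on well-separated 1-D samples recovers the optimal split", {
  beta <- matrix(c(0.0, 0.1, 0.2, 0.8, 0.9, 1.0), ncol = 1,
                 dimnames = list(paste0("s", 1:6), "g1"))
  fit <- kmeans_cluster(beta, k = 2, seed = 1)
  oracle <- enum_kmeans2(unname(beta))
  expect_equal(fit$within_cluster_ss, oracle$wss, tolerance = 1e-12)
  expect_equal(fit$cluster[1:3], rep(fit$cluster[1], 3))
  expect_equal(fit$cluster[4:6], rep(fit$cluster[4], 3))
  expect_true(fit$cluster[1] != fit$cluster[4])
})

test_that("two samples with k = 2 are forced into singleton clusters", {
  beta <- matrix(c(0.1, 0.9, 0.2, 0.8), 2,
                 dimnames = list(c("a", "b"), c("g1", "g2")))
  fit <- kmeans_cluster(beta, k = 2, seed = 3)
  expect_equal(sort(fit$cluster), c(1L, 2L))
  expect_equal(fit$within_cluster_ss, 0)
})

test_that("clustering is deterministic given the seed", {
  withr::with_seed(99, {
    beta <- matrix(runif(200), 20, 10,
                   dimnames = list(paste0("s", 1:20), paste0("g", 1:10)))
  })
  f1 <- kmeans_cluster(beta, k = 3, seed = 7)
  f2 <- kmeans_cluster(beta, k = 3, seed = 7)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$centroids, f2$centroids)
})

test_that("degenerate inputs are rejected", {
  beta <- matrix(0.5, 4, 3, dimnames = list(paste0("s", 1:4), paste0("g", 1:3)))
  expect_error(kmeans_cluster(beta, k = 2, seed = 1), "identical")
  b2 <- matrix(runif(12), 4, 3, dimnames = dimnames(beta))
  expect_error(kmeans_cluster(b2, k = 5, seed = 1), "exceeds")
  b2[1, 1] <- NA
  expect_error(kmeans_cluster(b2, k = 2, seed = 1), "missing")
})

test_that("small random instances attain the exhaustive-enumeration optimum", {
  for (i in 1:10) {
    withr::with_seed(1000 + i, {
      n <- sample(4:8, 1)
      p <- sample(1:3, 1)
      X <- matrix(runif(n * p), n, p,
                  dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
    })
    fit <- kmeans_cluster(X, k = 2, seed = i)
    oracle <- enum_kmeans2(unname(X))
    expect_equal(fit$within_cluster_ss, oracle$wss, tolerance = 1e-10)
  }
})

test_that("within-cluster SS is non-increasing over Lloyd iterations", {
  withr::with_seed(5, {
    beta <- matrix(rbeta(50 * 20, 2, 2), 50, 20,
                   dimnames = list(paste0("s", 1:50), paste0("g", 1:20)))
  })
  fit <- kmeans_cluster(beta, k = 4, seed = 2, n_restarts = 10)
  expect_true(all(diff(fit$wss_trace) <= 1e-8))
})

test_that("stats::kmeans agrees on a clearly separated instance", {
  co <- simulate_cohort(n_samples = 60, n_genes = 50, n_markers = 25,
                        delta_beta = 0.4, seed = 21)
  fit <- kmeans_cluster(co$beta, k = 2, seed = 4)
  ref <- withr::with_seed(4, stats::kmeans(co$beta, centers = 2, nstart = 25))
  expect_equal(fit$within_cluster_ss, ref$tot.withinss, tolerance = 1e-8)
  expect_equal(adjusted_rand_index(fit$cluster, ref$cluster), 1.0)
})

test_that("planted separation is recovered exactly (ARI = 1)", {
  co <- simulate_cohort(n_samples = 80, n_genes = 60, n_markers = 20,
                        delta_beta = 0.35, seed = 31)
  fit <- kmeans_cluster(co$beta, k = 2, seed = 6)
  fit <- label_extreme_phenotypes(fit, co$beta)
  expect_equal(adjusted_rand_index(fit$labels, co$truth$planted_labels), 1.0)
  # and the positive label lands on the hypermethylated phenotype
  expect_equal(unname(fit$labels[match(names(co$truth$planted_labels), fit$sample_ids)]),
               unname(co$truth$planted_labels))
})

test_that("extreme labeling follows centroid mean beta, with intermediates for k > 2", {
  withr::with_seed(8, {
    lo <- matrix(rbeta(10 * 5, 10, 40), 10, 5)   # mean ~ 0.2
    mid <- matrix(rbeta(10 * 5, 25, 25), 10, 5)  # mean ~ 0.5
    hi <- matrix(rbeta(10 * 5, 40, 10), 10, 5)   # mean ~ 0.8
  })
  beta <- rbind(lo, mid, hi)
  dimnames(beta) <- list(paste0("s", 1:30), paste0("g", 1:5))
  fit <- label_extreme_phenotypes(kmeans_cluster(beta, k = 3, seed = 9), beta)
  expect_equal(sort(unique(fit$labels)),
               c("CIMP_negative", "CIMP_positive", sort(grep("intermediate", fit$cluster_labels, value = TRUE))))
  expect_true(all(fit$labels[1:10] == "CIMP_negative"))
  expect_true(all(fit$labels[21:30] == "CIMP_positive"))
  expect_true(all(grepl("intermediate", fit$labels[11:20])))
  # positive centroid has strictly higher mean beta than negative
  cm <- rowMeans(fit$centroids)
  expect_gt(cm[fit$cluster_labels == "CIMP_positive"],
            cm[fit$cluster_labels == "CIMP_negative"])
})

test_that("an exact centroid-mean tie labels the larger cluster negative", {
  beta <- rbind(matrix(rep(c(0.2, 0.4), each = 4), 4),
                matrix(rep(c(0.4, 0.2), each = 2), 2))
  dimnames(beta) <- list(paste0("s", 1:6), c("g1", "g2"))
  fit <- kmeans_cluster(beta, k = 2, seed = 1)
  expect_warning(fit <- label_extreme_phenotypes(fit, beta), "tie")
  expect_equal(sum(fit$labels == "CIMP_negative"), 4L)
  expect_equal(sum(fit$labels == "CIMP_positive"), 2L)
})

test_that("cluster means are per-phenotype arithmetic means", {
  beta <- matrix(c(0.2, 0.4, 0.1, 0.3,
                   0.5, 0.5, 0.5, 0.5), ncol = 2,
                 dimnames = list(c("a", "b", "c", "d"), c("g1", "g2")))
  fake <- structure(list(sample_ids = c("a", "b", "c", "d"),
                         labels = c("CIMP_positive", "CIMP_positive",
                                    "CIMP_negative", "CIMP_negative")),
                    class = "cgp_assignment")
  cm <- cluster_means(beta, fake)
  expect_equal(cm$mean_positive[cm$gene == "g1"], 0.3)
  expect_equal(cm$mean_negative[cm$gene == "g1"], 0.2)
  # constant feature: equal means
  expect_equal(cm$mean_positive[cm$gene == "g2"], cm$mean_negative[cm$gene == "g2"])
  # a phenotype with zero samples errors
  fake$labels <- rep("CIMP_positive", 4)
  expect_error(cluster_means(beta, fake), "no samples")
})
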
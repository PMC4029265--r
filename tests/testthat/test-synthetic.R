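test_that("cohort dimensions and invariants hold", {
  co <- simulate_cohort(n_samples = 100, n_genes = 500, n_markers = 30, seed = 1)
  expect_equal(dim(co$beta), c(100L, 500L))
  expect_equal(dim(co$expression), c(100L, 500L))
  expect_equal(nrow(co$clinical), 100L)
  expect_true(all(co$beta >= 0 & co$beta <= 1))
  expect_true(all(co$clinical$survival_months >= 0))
  expect_true(all(co$clinical$event %in% c(0L, 1L)))
  expect_true(all(co$truth$marker_genes$gene %in% colnames(co$beta)))
  expect_gt(sum(co$truth$planted_labels == "CIMP_positive"), 0)
  expect_gt(sum(co$truth$planted_labels == "CIMP_negative"), 0)
})

test_that("a null cohort has no between-phenotype effects beyond noise", {
  co <- simulate_cohort(n_samples = 200, n_genes = 300, n_markers = 0,
                        delta_beta = 0, delta_expr = 0, hazard_ratio = 1,
                        frac_positive = 0.5, seed = 2)
  pos <- co$truth$planted_labels == "CIMP_positive"
  dhat <- colMeans(co$beta[pos, ]) - colMeans(co$beta[!pos, ])
  se <- sqrt(apply(co$beta[pos, ], 2, var) / sum(pos) +
             apply(co$beta[!pos, ], 2, var) / sum(!pos))
  expect_gte(mean(abs(dhat) < 4 * se), 0.99)
})

test_that("planted marker deltas are realized within sampling error", {
  co <- simulate_cohort(n_samples = 200, n_genes = 200, n_markers = 25,
                        delta_beta = 0.3, frac_positive = 0.5, seed = 3)
  pos <- co$truth$planted_labels == "CIMP_positive"
  mk <- co$truth$marker_genes
  dhat <- colMeans(co$beta[pos, mk$gene]) - colMeans(co$beta[!pos, mk$gene])
  expect_true(all(abs(dhat - mk$delta_beta) < 0.05))
  dexpr <- colMeans(co$expression[pos, mk$gene]) -
    colMeans(co$expression[!pos, mk$gene])
  expect_true(all(abs(dexpr - mk$delta_expr) < 0.6))
})

test_that("discordant decoys are hypermethylated but up-regulated, and filtered out", {
  co <- simulate_cohort(n_samples = 150, n_genes = 200, n_markers = 15,
                        n_discordant = 10, delta_beta = 0.3, seed = 4)
  fit <- label_extreme_phenotypes(kmeans_cluster(co$beta, 2, seed = 5), co$beta)
  panel <- filter_markers(link_by_gene(cluster_means(co$beta, fit),
                                       cluster_means(co$expression, fit)),
                          "hyper_down", 0.15, 1.0)
  expect_setequal(panel$gene, co$truth$marker_genes$gene)
  expect_length(intersect(panel$gene, co$truth$discordant_genes), 0)
})

test_that("realized censoring matches the target rate", {
  for (rate in c(0, 0.2, 0.4)) {
    co <- simulate_cohort(n_samples = 400, n_genes = 20, n_markers = 5,
                          censoring_rate = rate, seed = 6)
    expect_lt(abs(mean(co$clinical$event == 0) - rate), 0.07)
  }
})

test_that("the planted hazard ratio is recovered by the Cox fit", {
  co <- simulate_cohort(n_samples = 400, n_genes = 20, n_markers = 5,
                        hazard_ratio = 2, frac_positive = 0.5, seed = 7)
  fit <- cox_univariate(co$clinical$survival_months, co$clinical$event,
                        co$truth$planted_labels)
  expect_lt(abs(fit$coef - log(2)), 3 * fit$log_hr_se)
})

test_that("a fixed seed gives byte-identical cohort files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(simulate_cohort(n_samples = 40, n_genes = 30, seed = 9), d1)
  write_cohort(simulate_cohort(n_samples = 40, n_genes = 30, seed = 9), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("written cohorts round-trip through the io readers", {
  co <- simulate_cohort(n_samples = 30, n_genes = 25, n_markers = 5, seed = 10)
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_equal(read_beta_matrix(paths[["beta"]]), co$beta, tolerance = 1e-12)
  expect_equal(read_expression_matrix(paths[["expression"]]), co$expression,
               tolerance = 1e-12)
  clin <- read_clinical(paths[["clinical"]])
  expect_equal(clin$sample_id, co$clinical$sample_id)
  expect_equal(clin$survival_months, co$clinical$survival_months,
               tolerance = 1e-12)
  truth <- utils::read.delim(paths[["truth_markers"]], stringsAsFactors = FALSE)
  expect_setequal(truth$gene, co$truth$marker_genes$gene)
  expect_error(write_cohort(co, ""), "non-empty")
})

test_that("generator parameters are validated", {
  expect_error(simulate_cohort(n_markers = 50, n_genes = 20), "exceeds")
  expect_error(simulate_cohort(frac_positive = 1.2), "frac_positive")
  expect_error(simulate_cohort(censoring_rate = 1), "censoring_rate")
  expect_error(simulate_cohort(hazard_ratio = -1), "> 0")
})
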
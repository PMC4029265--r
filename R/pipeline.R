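# End-to-end orchestration: read/align -> probe aggregation -> panel
# restriction -> imputation -> k-means + extreme labeling -> cluster means
# -> concordance filter -> survival tests -> bootstrap stability ->
# random-gene null. One seed in the config drives every stage; reports
# carry no timestamps, so a fixed config reproduces byte-identical output.

#' Build and validate a pipeline run configuration
#'
#' Inputs may be file paths (TSV, read with the io functions) or in-memory
#' objects (matrices / data frames) — convenient when chaining from
#' [simulate_cohort()].
#'
#' @param beta beta matrix path or samples-by-features matrix.
#' @param expression expression matrix path or matrix.
#' @param clinical clinical table path or data frame.
#' @param probe_map optional probe-to-gene map (path or data frame); when
#'   given, beta probes are aggregated to genes before any panel
#'   restriction.
#' @param gene_panel optional gene panel (path to a one-symbol-per-line
#'   file, or character vector) restricting the feature universe of both
#'   matrices.
#' @param k number of clusters (default 2).
#' @param seed single integer seed for every random stage.
#' @param n_restarts k-means++ restarts for the main clustering.
#' @param direction,delta_beta_min,delta_expr_min marker filter settings
#'   (see [filter_markers()]).
#' @param bootstrap_iterations,random_test_iterations resampling iteration
#'   counts (default 1000 each).
#' @param validation_restarts k-means++ restarts inside the resampling
#'   loops (default 5).
#' @param max_missing_frac missingness threshold for [impute_missing()].
#' @param orientation on-disk matrix orientation when reading from paths.
#' @param clinical_columns named character vector mapping `id`, `time`,
#'   `event` to clinical column names.
#' @param out_dir optional output directory; when set, [run_pipeline()]
#'   writes all per-stage TSVs plus `report.txt` / `report.json` there.
#' @return a validated `cgp_config` list echoing every effective setting.
#' @export
run_config <- function(beta, expression, clinical,
                       probe_map = NULL, gene_panel = NULL,
                       k = 2L, seed = 1L, n_restarts = 20L,
                       direction = "both", delta_beta_min = 0.1,
                       delta_expr_min = 0,
                       bootstrap_iterations = 1000L,
                       random_test_iterations = 1000L,
                       validation_restarts = 5L,
                       max_missing_frac = 0.2,
                       orientation = "features_in_rows",
                       clinical_columns = c(id = "sample_id",
                                            time = "survival_months",
                                            event = "event"),
                       out_dir = NULL) {
  if (k < 2L) stop_cgp("k must be >= 2")
  if (bootstrap_iterations < 1L || random_test_iterations < 1L) {
    stop_cgp("iteration counts must be >= 1")
  }
  if (delta_beta_min < 0 || delta_expr_min < 0) stop_cgp("thresholds must be >= 0")
  direction <- match.arg(direction, c("both", "hyper_down", "hypo_up"))
  orientation <- match.arg(orientation, c("features_in_rows", "samples_in_rows"))
  structure(list(beta = beta, expression = expression, clinical = clinical,
                 probe_map = probe_map, gene_panel = gene_panel,
                 k = as.integer(k), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 direction = direction,
                 delta_beta_min = delta_beta_min,
                 delta_expr_min = delta_expr_min,
                 bootstrap_iterations = as.integer(bootstrap_iterations),
                 random_test_iterations = as.integer(random_test_iterations),
                 validation_restarts = as.integer(validation_restarts),
                 max_missing_frac = max_missing_frac,
                 orientation = orientation,
                 clinical_columns = clinical_columns,
                 out_dir = out_dir),
            class = "cgp_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_cgp("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

config_echo <- function(config) {
  echo <- unclass(config)
  for (nm in c("beta", "expression", "clinical", "probe_map", "gene_panel")) {
    if (!is.null(echo[[nm]]) && !is.character(echo[[nm]])) {
      echo[[nm]] <- sprintf("<in-memory %s>", class(echo[[nm]])[1L])
    }
  }
  echo$clinical_columns <- as.list(echo$clinical_columns)
  echo$out_dir <- NULL # location-independent: reports are byte-stable across directories
  echo
}

#' Run the full marker-panel discovery and validation pipeline
#'
#' Executes, in order: input reading, optional probe-to-gene aggregation,
#' optional gene-panel restriction (of both matrices), missing-value
#' handling, sample alignment, k-means clustering with extreme-phenotype
#' labeling, per-phenotype cluster means, the concordance marker filter,
#' log-rank and Cox survival tests of CIMP-positive vs CIMP-negative,
#' bootstrap cluster stability, and the random-gene-selection null (using
#' the phenotype log-rank chi-square as the observed statistic; skipped
#' with a logged warning when the panel is empty). Fully reproducible from
#' `(config, seed)`. When `config$out_dir` is set, per-stage TSVs plus a
#' text and a JSON report are written there.
#'
#' @param config a `cgp_config` from [run_config()].
#' @return a `cgp_report` list with the assignment, panel, survival tests,
#'   KM curves, bootstrap and random-test results, and the echoed config.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "cgp_config")) stop_cgp("config must come from run_config()")
  beta <- with_stage("read_beta", {
    if (is.character(config$beta)) {
      read_beta_matrix(config$beta, config$orientation)
    } else config$beta
  })
  expression <- with_stage("read_expression", {
    if (is.character(config$expression)) {
      read_expression_matrix(config$expression, config$orientation)
    } else config$expression
  })
  clinical <- with_stage("read_clinical", {
    if (is.character(config$clinical)) {
      cc <- config$clinical_columns
      read_clinical(config$clinical, id_col = cc[["id"]],
                    time_col = cc[["time"]], event_col = cc[["event"]])
    } else config$clinical
  })
  if (!is.null(config$probe_map)) {
    beta <- with_stage("probe_aggregation", {
      pm <- if (is.character(config$probe_map)) read_probe_map(config$probe_map) else config$probe_map
      aggregate_probes_to_genes(beta, pm)
    })
  }
  if (!is.null(config$gene_panel)) {
    panel_genes <- if (is.character(config$gene_panel) && length(config$gene_panel) == 1L &&
                       file.exists(config$gene_panel)) {
      read_gene_list(config$gene_panel)
    } else config$gene_panel
    beta <- with_stage("panel_restriction", restrict_to_panel(beta, panel_genes))
    expression <- with_stage("panel_restriction", restrict_to_panel(expression, panel_genes))
  }
  beta <- with_stage("imputation", impute_missing(beta, config$max_missing_frac))
  aligned <- with_stage("sample_alignment", align_samples(beta, expression, clinical))
  beta <- aligned$beta
  expression <- aligned$expression
  clinical <- aligned$clinical

  assignment <- with_stage("clustering", {
    fit <- kmeans_cluster(beta, k = config$k, seed = derive_seed(config$seed, 1L),
                          n_restarts = config$n_restarts)
    label_extreme_phenotypes(fit, beta)
  })
  meth_means <- with_stage("cluster_means", cluster_means(beta, assignment))
  expr_means <- with_stage("cluster_means", cluster_means(expression, assignment))
  panel <- with_stage("marker_filter", {
    filter_markers(link_by_gene(meth_means, expr_means),
                   direction = config$direction,
                   delta_beta_min = config$delta_beta_min,
                   delta_expr_min = config$delta_expr_min)
  })

  two_group <- assignment$labels %in% c("CIMP_positive", "CIMP_negative")
  surv_clin <- clinical[two_group, , drop = FALSE]
  surv_lab <- assignment$labels[two_group]
  logrank <- with_stage("survival", {
    logrank_test(surv_clin$survival_months, surv_clin$event, surv_lab)
  })
  cox <- with_stage("survival", {
    cox_univariate(surv_clin$survival_months, surv_clin$event, surv_lab)
  })
  km <- with_stage("survival", {
    km_by_group(surv_clin$survival_months, surv_clin$event, surv_lab)
  })
  boot <- with_stage("bootstrap", {
    bootstrap_stability(beta, assignment$clustering_features, assignment,
                        iterations = config$bootstrap_iterations,
                        seed = derive_seed(config$seed, 2L),
                        n_restarts = config$validation_restarts)
  })
  random_test <- NULL
  if (nrow(panel) >= 1L) {
    random_test <- with_stage("random_gene_test", {
      random_gene_test(beta, clinical, panel_size = nrow(panel),
                       gene_universe = colnames(beta),
                       iterations = config$random_test_iterations,
                       seed = derive_seed(config$seed, 3L),
                       observed_statistic = logrank$chi_square,
                       n_restarts = config$validation_restarts)
    })
  } else {
    cgp_log("warning: empty predictor panel; random-gene test skipped")
  }

  report <- structure(list(
    phenotype_sizes = as.list(table(assignment$labels)),
    assignment = assignment,
    panel = panel,
    logrank = logrank,
    cox = cox,
    km_curves = km,
    bootstrap = boot,
    random_test = random_test,
    config = config_echo(config),
    package_version = as.character(utils::packageVersion("cimpanel"))
  ), class = "cgp_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

report_summary <- function(report) {
  list(
    phenotype_sizes = report$phenotype_sizes,
    panel_size = nrow(report$panel),
    panel_genes = report$panel$gene,
    logrank = list(chi_square = report$logrank$chi_square,
                   p_value = report$logrank$p_value),
    cox = list(hazard_ratio = report$cox$hazard_ratio,
               log_hr_se = report$cox$log_hr_se,
               wald_chi_square = report$cox$chi_square,
               wald_p_value = report$cox$p_value,
               score_chi_square = report$cox$score_chi_square,
               score_p_value = report$cox$score_p_value,
               infinite_hr = report$cox$infinite_hr),
    bootstrap = list(iterations = report$bootstrap$iterations,
                     mean_sensitivity = report$bootstrap$mean_sensitivity,
                     chance_level = report$bootstrap$chance_level,
                     empirical_p = report$bootstrap$empirical_p),
    random_test = if (!is.null(report$random_test)) {
      list(iterations = report$random_test$iterations,
           panel_size = report$random_test$panel_size,
           observed_chi_square = report$random_test$observed_statistic,
           empirical_p = report$random_test$empirical_p)
    },
    config = report$config,
    package_version = report$package_version
  )
}

#' Write a pipeline report and its per-stage tables to a directory
#'
#' @param report a `cgp_report` from [run_pipeline()].
#' @param out_dir output directory (created if absent).
#' @return named vector of files written, invisibly.
#' @export
write_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  a <- report$assignment
  files <- c(
    assignment = write_table_tsv(
      data.frame(sample_id = a$sample_ids, phenotype = a$labels,
                 stringsAsFactors = FALSE),
      file.path(out_dir, "assignment.tsv")),
    centroids = write_matrix_tsv(a$centroids, file.path(out_dir, "centroids.tsv"),
                                 orientation = "samples_in_rows",
                                 id_label = "cluster"),
    panel = write_table_tsv(as.data.frame(report$panel),
                            file.path(out_dir, "panel.tsv")),
    km_curves = write_table_tsv(report$km_curves,
                                file.path(out_dir, "km_curves.tsv")),
    bootstrap = write_table_tsv(
      data.frame(iteration = seq_along(report$bootstrap$sensitivities),
                 sensitivity = report$bootstrap$sensitivities),
      file.path(out_dir, "bootstrap_iterations.tsv"))
  )
  if (!is.null(report$random_test)) {
    files["random_test"] <- write_table_tsv(
      data.frame(iteration = seq_along(report$random_test$null_statistics),
                 chi_square = report$random_test$null_statistics),
      file.path(out_dir, "random_test_iterations.tsv"))
  }
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_summary(report), json_path,
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  txt_path <- file.path(out_dir, "report.txt")
  txt <- utils::capture.output(print(report))
  writeLines(txt, txt_path)
  files["report_json"] <- json_path
  files["report_txt"] <- txt_path
  invisible(files)
}

#' @export
print.cgp_report <- function(x, ...) {
  cat("== CIMP marker-panel pipeline report ==\n")
  cat(sprintf("seed: %d | k: %d | package: cimpanel %s\n",
              x$config$seed, x$config$k, x$package_version))
  cat("phenotype sizes: ",
      paste(sprintf("%s = %d", names(x$phenotype_sizes),
                    unlist(x$phenotype_sizes)), collapse = ", "), "\n", sep = "")
  cat(sprintf("predictor panel: %d gene(s)\n", nrow(x$panel)))
  if (nrow(x$panel) > 0L) {
    cat("  ", paste(utils::head(x$panel$gene, 10L), collapse = ", "),
        if (nrow(x$panel) > 10L) ", ..." else "", "\n", sep = "")
  }
  print(x$logrank)
  print(x$cox)
  print(x$bootstrap)
  if (!is.null(x$random_test)) print(x$random_test) else
    cat("random-gene test: skipped (empty panel)\n")
  invisible(x)
}
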
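## End-to-end orchestration: simulate -> preprocess -> features -> classify,
## with open-format artifacts and a reproducibility manifest.

#' Pipeline run configuration
#'
#' Every tunable defaults to the protocol value used throughout the package:
#' sample entropy m = 1, r = 0.1 x SD; TE history k = l = 1, t = 1,
#' tau = 1..5; RBF-SVM sigma = 4; 1000 CV repeats; 10% quality gate; cohort
#' of 16 cases (4 of them corrupted beyond the gate) and 19 controls so the
#' preprocessing attrition to 12 + 19 is exercised.
#'
#' @param seed master seed; fans out deterministically to every stage.
#' @param n_cases,n_controls recruited group sizes.
#' @param n_corrupted_cases cases injected with >10% HR artifacts.
#' @param corrupted_artifact_rate artifact rate for those cases.
#' @param record_days recording length per subject.
#' @param dropout_rate baseline dropout rate for all subjects.
#' @param gate quality-gate threshold.
#' @param m,r_fraction sample-entropy parameters.
#' @param taus TE source lags.
#' @param te_alpha,te_min_expected Darbellay-Vajda splitting controls.
#' @param te_min_triples minimum usable TE triples.
#' @param sigma,cost SVM parameters.
#' @param n_repeats CV repeats.
#' @param k_max largest mRMR prefix examined.
#' @param profiles calibration profiles, default [calibration_profiles()].
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1, n_cases = 16, n_controls = 19,
                       n_corrupted_cases = 4, corrupted_artifact_rate = 0.15,
                       record_days = 14, dropout_rate = 0.02, gate = 0.10,
                       m = 1, r_fraction = 0.1, taus = 1:5, te_alpha = 0.05,
                       te_min_expected = 5, te_min_triples = 500,
                       sigma = 4, cost = 1, n_repeats = 1000, k_max = 10,
                       profiles = NULL) {
  structure(list(seed = seed, n_cases = n_cases, n_controls = n_controls,
                 n_corrupted_cases = n_corrupted_cases,
                 corrupted_artifact_rate = corrupted_artifact_rate,
                 record_days = record_days, dropout_rate = dropout_rate,
                 gate = gate, m = m, r_fraction = r_fraction, taus = taus,
                 te_alpha = te_alpha, te_min_expected = te_min_expected,
                 te_min_triples = te_min_triples, sigma = sigma, cost = cost,
                 n_repeats = n_repeats, k_max = k_max,
                 profiles = profiles %||% calibration_profiles()),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic cohort, corrupts the configured subset of cases,
#' writes the long-format cohort CSV, preprocesses every subject, extracts
#' the 36-feature matrix, performs the Wilcoxon-Bonferroni group
#' comparison, and runs the three feature-set experiments. All artifacts are
#' written to `out_dir` in open formats (CSV/JSON) together with a manifest
#' recording the configuration, per-stage counts and rejected subjects.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param write_cohort write the raw cohort CSV (large); default TRUE.
#' @return invisibly, a list with `features`, `comparison`, `experiments`,
#'   `rejected`, `manifest`, `paths`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("cardioact_run_"),
                         write_cohort = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 4)

  acq_clean <- acquisition_model(dropout_rate = config$dropout_rate,
                                 record_days = config$record_days)
  cohort <- generate_cohort(config$n_cases, config$n_controls,
                            config$profiles$case, config$profiles$control,
                            acq_clean, seed = seeds[1])
  if (config$n_corrupted_cases > 0) {
    acq_bad <- acquisition_model(dropout_rate = 0,
                                 artifact_rate = config$corrupted_artifact_rate,
                                 record_days = config$record_days)
    bad_seeds <- derive_seeds(seeds[2], config$n_corrupted_cases)
    for (i in seq_len(config$n_corrupted_cases)) {
      cohort[[i]] <- inject_artifacts(cohort[[i]], acq_bad, seed = bad_seeds[i])
    }
  }
  paths <- list()
  if (write_cohort) {
    paths$cohort <- file.path(out_dir, "cohort.csv")
    write_cohort_csv(cohort, paths$cohort)
  }

  prep <- preprocess_cohort(cohort, gate = config$gate)
  qc <- lapply(prep$accepted, function(s) {
    c(list(subject_id = s$subject_id, label = s$label), s$qc)
  })
  paths$preprocess_report <- file.path(out_dir, "preprocess_report.json")
  jsonlite::write_json(list(accepted = qc, rejected = prep$rejected),
                       paths$preprocess_report, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  fm <- feature_matrix(prep$accepted, m = config$m, r_fraction = config$r_fraction,
                       te_args = list(taus = config$taus, alpha = config$te_alpha,
                                      min_expected = config$te_min_expected,
                                      min_triples = config$te_min_triples))
  paths$features <- file.path(out_dir, "features.csv")
  write.csv(fm, paths$features, row.names = FALSE)

  comparison <- group_compare(fm)
  paths$comparison <- file.path(out_dir, "group_comparison.csv")
  write.csv(comparison, paths$comparison, row.names = FALSE)

  cfg_cls <- classifier_config(sigma = config$sigma, cost = config$cost)
  experiments <- run_feature_set_experiments(fm, cfg_cls, k_max = config$k_max,
                                             n_repeats = config$n_repeats,
                                             seed = seeds[3])
  for (nm in names(experiments)) {
    e <- experiments[[nm]]
    write.csv(e$ranking, file.path(out_dir, sprintf("ranking_%s.csv", nm)),
              row.names = FALSE)
    write.csv(e$cv$roc, file.path(out_dir, sprintf("roc_%s.csv", nm)),
              row.names = FALSE)
    jsonlite::write_json(
      list(set = nm, best_k = e$best_k, selected = e$selected,
           accuracy = e$cv$accuracy, sensitivity = e$cv$sensitivity,
           specificity = e$cv$specificity, auc = e$cv$auc,
           n_repeats = e$cv$n_repeats, seed = e$cv$seed),
      file.path(out_dir, sprintf("metrics_%s.json", nm)),
      auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("cardioact")),
    seed = config$seed,
    config = config[setdiff(names(config), "profiles")],
    profiles_version = config$profiles$version,
    n_generated = length(cohort),
    n_accepted = length(prep$accepted),
    n_rejected = nrow(prep$rejected),
    rejected = prep$rejected,
    n_features = length(feature_names())
  )
  paths$manifest <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")

  invisible(list(features = fm, comparison = comparison,
                 experiments = experiments, rejected = prep$rejected,
                 manifest = manifest, paths = paths, out_dir = out_dir))
}

#' Render a human-readable run summary
#'
#' Builds the per-feature table (group mean +/- SD, mRMR rank in the fused
#' set, Bonferroni significance flag) and the three-experiment comparison
#' from a completed run directory or an in-memory [run_pipeline()] result.
#'
#' @param run a run directory path or the list returned by [run_pipeline()].
#' @return a `run_report` list with `feature_table` and `experiment_table`;
#'   printed as two aligned tables.
#' @export
render_report <- function(run) {
  if (is.character(run)) {
    dirp <- run
    fpath <- file.path(dirp, "features.csv")
    if (!file.exists(fpath)) stop("incomplete run: missing features.csv", call. = FALSE)
    fm <- read.csv(fpath)
    comparison <- read.csv(file.path(dirp, "group_comparison.csv"))
    ranking <- read.csv(file.path(dirp, "ranking_fused.csv"))
    metrics <- lapply(c("hr", "activity", "fused"), function(nm) {
      jsonlite::read_json(file.path(dirp, sprintf("metrics_%s.json", nm)),
                          simplifyVector = TRUE)
    })
  } else {
    fm <- run$features
    comparison <- run$comparison
    ranking <- run$experiments$fused$ranking
    metrics <- lapply(run$experiments, function(e) {
      list(set = NA, best_k = e$best_k, selected = e$selected,
           accuracy = e$cv$accuracy, sensitivity = e$cv$sensitivity,
           specificity = e$cv$specificity, auc = e$cv$auc)
    })
    for (i in seq_along(metrics)) metrics[[i]]$set <- names(run$experiments)[i]
  }
  if (length(unique(fm$label)) < 2) {
    warning("cohort contains a single group; group columns collapse")
  }
  grp_stat <- function(v, lab) {
    x <- v[fm$label == lab]
    sprintf("%.3g ± %.2g", mean(x, na.rm = TRUE), sd(x, na.rm = TRUE))
  }
  feats <- intersect(feature_names(), names(fm))
  feature_table <- data.frame(
    feature = feats,
    case = vapply(fm[feats], grp_stat, character(1), lab = 1),
    control = vapply(fm[feats], grp_stat, character(1), lab = 0),
    mrmr_rank = match(feats, ranking$feature),
    significant = comparison$significant[match(feats, comparison$feature)]
  )
  experiment_table <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(set = m$set, best_k = m$best_k,
               selected = paste(unlist(m$selected), collapse = ", "),
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, auc = m$auc)
  }))
  structure(list(feature_table = feature_table,
                 experiment_table = experiment_table),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Per-feature summary (group mean ± SD, fused mRMR rank, Bonferroni flag)\n")
  print(x$feature_table, row.names = FALSE)
  cat("\nClassification experiments\n")
  print(x$experiment_table, row.names = FALSE)
  invisible(x)
}

#' Plot pooled ROC curves of the three experiments
#'
#' @param experiments an `experiment_set` from [run_feature_set_experiments()].
#' @return invisibly, NULL; draws on the current graphics device.
#' @export
plot_roc <- function(experiments) {
  cols <- c(hr = "grey40", activity = "steelblue", fused = "firebrick")
  plot(0:1, 0:1, type = "l", lty = 3, col = "grey70",
       xlab = "False positive rate", ylab = "True positive rate")
  for (nm in names(experiments)) {
    e <- experiments[[nm]]
    graphics::lines(e$cv$roc$fpr, e$cv$roc$tpr, col = cols[[nm]] %||% "black", lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2, col = unname(cols[names(experiments)]),
                   legend = sprintf("%s (AUC %.2f)", names(experiments),
                                    vapply(experiments, function(e) e$cv$auc, numeric(1))))
  invisible(NULL)
}
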
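#' Read a sample-by-feature matrix from TSV
#'
#' Expects a header row of feature ids and a first column of sample ids.
#' Duplicate sample or feature ids and non-numeric cells are rejected
#' with the offending coordinates; sample order is preserved.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with rownames (samples) and colnames
#'   (features).
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected a sample-id column plus features")
  ids <- as.character(df[[1L]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicated sample id(s): ", paste(unique(dup), collapse = ", "))
  }
  feats <- colnames(df)[-1L]
  dupf <- feats[duplicated(feats)]
  if (length(dupf) > 0L) {
    stop("duplicated feature id(s): ", paste(unique(dupf), collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  if (anyNA(vals)) stop("missing values in feature matrix")
  for (j in seq_along(vals)) {
    if (!is.numeric(vals[[j]])) {
      conv <- suppressWarnings(as.numeric(vals[[j]]))
      bad <- which(is.na(conv))[1L]
      stop(sprintf("non-numeric cell at sample '%s', feature '%s'",
                   ids[bad], feats[j]))
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  m
}

#' Write a sample-by-feature matrix as TSV
#'
#' @param m Numeric matrix with rownames and colnames.
#' @param path Output path.
#' @param id_col Name for the sample-id column (default `"sample_id"`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, path, id_col = "sample_id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a cohort to a directory of plain-text files
#'
#' Writes `phenotype.tsv`, one `<layer>.tsv` per feature layer, and
#' (when a truth object is supplied) `truth.json`.
#'
#' @param cohort An `omics_cohort`.
#' @param dir Output directory (created if needed).
#' @param truth Optional `synthetic_truth`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  stopifnot(inherits(cohort, "omics_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$phenotype, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(cohort$layers)) {
    write_feature_matrix(cohort$layers[[nm]],
                         file.path(dir, paste0(nm, ".tsv")))
  }
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Join a feature matrix to a phenotype table, strictly
#'
#' Strict sample-id join: the sample sets must match exactly; any
#' orphan on either side is an error (silent sample loss is the classic
#' multi-omics bug). Rows of the matrix are reordered to the phenotype
#' order.
#'
#' @param m Feature matrix with sample rownames.
#' @param phenotype Data frame with a `sample_id` column.
#' @return The matrix reordered to `phenotype$sample_id`.
#' @export
join_to_phenotype <- function(m, phenotype) {
  only_m <- setdiff(rownames(m), phenotype$sample_id)
  only_p <- setdiff(phenotype$sample_id, rownames(m))
  if (length(only_m) > 0L || length(only_p) > 0L) {
    stop("sample-id mismatch; orphans in matrix: [",
         paste(only_m, collapse = ", "), "]; orphans in phenotype: [",
         paste(only_p, collapse = ", "), "]")
  }
  m[phenotype$sample_id, , drop = FALSE]
}

#' Run the full biomarker-panel discovery pipeline
#'
#' Orchestrates the stages end to end on a synthetic cohort: simulate ->
#' (optionally) per-layer contribution -> repeated CV over the nasal
#' candidates -> rank-product feature ordering -> incremental panel
#' selection with the corrected CV stopping test -> final panel refit on
#' the full cohort -> evaluation. All artifacts are written under
#' `out_dir` as TSV/JSON with the master seed and configuration echoed.
#'
#' @param config A [sim_config()] describing the synthetic cohort.
#' @param out_dir Output directory.
#' @param settings [cv_settings()] used for ranking, selection and
#'   evaluation.
#' @param max_size Largest panel size explored (default 10).
#' @param stop_alpha Stopping level of the corrected CV test (default
#'   0.05).
#' @param layers Run the sequential layer-contribution stage (default
#'   FALSE; it multiplies the CV cost by the number of layers).
#' @param threshold Probability threshold for confusion metrics.
#' @return A list with the stage outputs (`cohort`, `truth`,
#'   `contributions` or NULL, `rank_table`, `path`, `panel`,
#'   `metrics`), invisibly; files are the primary product.
#' @export
run_pipeline <- function(config, out_dir, settings = cv_settings(),
                         max_size = 10, stop_alpha = 0.05,
                         layers = FALSE, threshold = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  stage <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s",
                                       format(Sys.time(), "%H:%M:%S"), msg))
  }

  stage("simulate")
  sim <- simulate_cohort(config)
  cohort <- sim$cohort
  write_cohort(cohort, file.path(out_dir, "cohort"), truth = sim$truth)
  y <- cohort$phenotype$allergy

  contributions <- NULL
  if (layers) {
    stage("layer contribution")
    contributions <- sequential_contribution(cohort, settings = settings)
    utils::write.table(contributions,
                       file.path(out_dir, "contributions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  stage("repeated CV over nasal candidates")
  nasal <- cohort$layers$nasal_meth
  cv_full <- repeated_cv(nasal, y, settings = settings)

  stage("rank product")
  rt <- rank_product(cv_full$importances)
  utils::write.table(rt, file.path(out_dir, "rank_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("incremental selection")
  path <- incremental_selection(nasal, y, rt$feature,
                                max_size = max_size,
                                stop_alpha = stop_alpha,
                                settings = settings)
  utils::write.table(path$path, file.path(out_dir, "path.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  stage("final panel refit on full cohort")
  sel_cv <- path$cv_results[[path$selected_size]]
  hp <- c(alpha = stats::median(sel_cv$runs$alpha),
          lambda = stats::median(sel_cv$runs$lambda))
  panel <- fit_penalized_logistic(
    nasal[, path$selected_features, drop = FALSE], y,
    alpha = unname(hp["alpha"]), lambda = unname(hp["lambda"]))
  write_panel_model(panel, file.path(out_dir, "panel.json"))

  stage("evaluation")
  prob <- predict_probability(panel, nasal)
  metrics <- list(
    cv_test_auc = sel_cv$summary$mean_test_auc,
    cv_train_auc = sel_cv$summary$mean_train_auc,
    cv_test_prc = sel_cv$summary$mean_test_prc,
    overfit_gap = sel_cv$summary$overfit_gap,
    apparent_auc = roc_auc(prob, y),
    apparent_prc = prc_auc(prob, y),
    confusion = confusion_at_threshold(prob, y, threshold))

  summary <- list(
    config = unclass(config),
    cv = list(k = settings$k, r = settings$r, tuning = settings$tuning,
              seed = settings$seed),
    selection = list(max_size = max_size, stop_alpha = stop_alpha,
                     selected_size = path$selected_size,
                     selected_features = path$selected_features),
    metrics = metrics,
    provenance = list(seed = config$seed,
                      package_version =
                        as.character(utils::packageVersion("methpanel"))))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(cohort = cohort, truth = sim$truth,
                 contributions = contributions, rank_table = rt,
                 path = path, panel = panel, metrics = metrics))
}
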
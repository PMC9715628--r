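#' Rank-product aggregation of per-run feature importances
#'
#' Within each cross-validation run, features are ranked by importance
#' (rank 1 = most important; tied importances, including the typically
#' large block of zero-coefficient features, receive average ranks). The
#' rank product of a feature is the geometric mean of its ranks over all
#' runs; small values mark features that are consistently top-ranked.
#'
#' @param importances Matrix of nonnegative importances, runs x features
#'   (as in `cv_result$importances`), with column names.
#' @return A data frame of class `rank_table`, sorted ascending by rank
#'   product, with columns `feature`, `rank_product`, and
#'   `mean_importance`; ties in rank product are broken by mean
#'   importance then feature name, so the ordering is total and
#'   deterministic.
#' @export
rank_product <- function(importances) {
  importances <- as.matrix(importances)
  if (nrow(importances) < 1L) stop("at least one run is required")
  if (is.null(colnames(importances))) stop("importances must name features")
  if (anyNA(importances)) stop("missing importances")
  # rank within each run: largest importance -> rank 1, ties averaged
  ranks <- t(apply(importances, 1L, function(v) {
    rank(-v, ties.method = "average")
  }))
  if (ncol(importances) == 1L) ranks <- t(ranks)
  rp <- exp(colMeans(log(ranks)))
  out <- data.frame(feature = colnames(importances),
                    rank_product = unname(rp),
                    mean_importance = unname(colMeans(importances)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_product, -out$mean_importance, out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("rank_table", "data.frame")
  out
}

#' Corrected repeated k-fold cross-validation t-test
#'
#' Paired comparison of two learners over the k*r runs of a repeated
#' k-fold CV. Because training sets overlap across runs, the naive paired
#' t-test is anti-conservative; the corrected statistic inflates the
#' variance by the test/train size ratio:
#' \deqn{t = \bar d / \sqrt{(1/(kr) + n_2/n_1)\,\hat\sigma^2}}
#' with \eqn{\hat\sigma^2} the usual (m-1)-denominator sample variance of
#' the m = k*r paired differences, referred to a Student t distribution
#' with k*r - 1 degrees of freedom (two-sided).
#'
#' @param diffs Numeric vector of the m = k*r per-run paired metric
#'   differences (e.g. test-AUC of model A minus model B on the same
#'   fold).
#' @param k Folds per repeat.
#' @param r Repeats.
#' @param test_train_ratio Ratio n2/n1 of test to training set size;
#'   default `1/(k-1)`, the k-fold value.
#' @return A list of class `corrected_cv_test`: `mean_diff`, `variance`,
#'   `t`, `df`, `p_value`, `k`, `r`, `test_train_ratio`, and `degenerate`
#'   (TRUE when all differences are identical, in which case p is 1 for a
#'   zero mean and 0 otherwise).
#' @references Nadeau & Bengio's variance correction for resampled
#'   statistics, in the repeated k-fold parameterization of Bouckaert &
#'   Frank.
#' @export
corrected_cv_ttest <- function(diffs, k, r, test_train_ratio = 1 / (k - 1)) {
  m <- k * r
  if (length(diffs) != m) {
    stop(sprintf("expected k*r = %d differences, got %d", m, length(diffs)))
  }
  if (m < 2L) stop("need at least 2 differences")
  if (test_train_ratio <= 0) stop("test_train_ratio must be > 0")
  d_bar <- mean(diffs)
  s2 <- stats::var(diffs)
  degenerate <- (s2 == 0)
  if (degenerate) {
    t_stat <- if (d_bar == 0) 0 else sign(d_bar) * Inf
    p <- if (d_bar == 0) 1 else 0
  } else {
    t_stat <- d_bar / sqrt((1 / m + test_train_ratio) * s2)
    p <- 2 * stats::pt(-abs(t_stat), df = m - 1)
  }
  structure(list(mean_diff = d_bar, variance = s2, t = t_stat, df = m - 1,
                 p_value = p, k = k, r = r,
                 test_train_ratio = test_train_ratio,
                 degenerate = degenerate),
            class = "corrected_cv_test")
}

#' @export
print.corrected_cv_test <- function(x, ...) {
  cat(sprintf(
    "corrected repeated %d-fold cv test (r = %d): mean diff %.4f, t = %.3f, df = %d, p = %.3g\n",
    x$k, x$r, x$mean_diff, x$t, x$df, x$p_value))
  invisible(x)
}

#' Incremental panel construction with a significance stopping rule
#'
#' Starting from the top rank-product feature, features are added one at
#' a time; each panel size is evaluated by repeated CV on a shared fold
#' plan (so per-run AUCs pair across sizes), and the gain from size s to
#' s+1 is tested with the corrected repeated k-fold CV test. The selected
#' size s* is the smallest s whose increment is non-significant at
#' `stop_alpha` -- i.e. growth continues only while additions still help
#' significantly. The full path is returned for audit regardless of
#' where the rule stops.
#'
#' @param X Feature matrix containing the candidate features.
#' @param y Binary outcome.
#' @param ranked_features Character vector of candidate features in rank
#'   order (e.g. `rank_table$feature`).
#' @param max_size Largest panel size to evaluate.
#' @param stop_alpha Significance level of the stopping test (default
#'   0.05).
#' @param settings A [cv_settings()]; its seed fixes the shared fold
#'   plan.
#' @return A list of class `incremental_path`: `path` (data frame with
#'   size, added feature, mean test AUC, and the p-value of the test
#'   against the previous size), `tests` (the `corrected_cv_test`
#'   objects), `cv_results` (one `cv_result` per size), `selected_size`,
#'   and `selected_features`.
#' @export
incremental_selection <- function(X, y, ranked_features, max_size,
                                  stop_alpha = 0.05,
                                  settings = cv_settings()) {
  X <- as_feature_matrix(X)
  ranked_features <- as.character(ranked_features)
  if (length(ranked_features) == 0L) stop("ranked_features is empty")
  missing <- setdiff(ranked_features, colnames(X))
  if (length(missing) > 0L) {
    stop("ranked features absent from X: ", paste(missing, collapse = ", "))
  }
  max_size <- as.integer(min(max_size, length(ranked_features)))
  folds <- make_fold_plan(y, settings)

  cv_results <- vector("list", max_size)
  tests <- vector("list", max_size - 1L)
  mean_auc <- numeric(max_size)
  p_vs_prev <- rep(NA_real_, max_size)
  selected <- max_size
  stopped <- FALSE
  for (s in seq_len(max_size)) {
    feats <- ranked_features[seq_len(s)]
    cv_results[[s]] <- repeated_cv(X[, feats, drop = FALSE], y,
                                   settings = settings, folds = folds)
    mean_auc[s] <- cv_results[[s]]$summary$mean_test_auc
    if (s > 1L) {
      d <- cv_results[[s]]$runs$test_auc - cv_results[[s - 1L]]$runs$test_auc
      tst <- corrected_cv_ttest(d, k = settings$k, r = settings$r)
      tests[[s - 1L]] <- tst
      p_vs_prev[s] <- tst$p_value
      if (!stopped && tst$p_value >= stop_alpha) {
        selected <- s - 1L
        stopped <- TRUE
      }
    }
  }
  path <- data.frame(size = seq_len(max_size),
                     feature_added = ranked_features[seq_len(max_size)],
                     mean_test_auc = mean_auc,
                     p_vs_previous = p_vs_prev,
                     stringsAsFactors = FALSE)
  structure(list(path = path, tests = tests, cv_results = cv_results,
                 selected_size = selected,
                 selected_features = ranked_features[seq_len(selected)],
                 stop_alpha = stop_alpha),
            class = "incremental_path")
}

#' @export
print.incremental_path <- function(x, ...) {
  cat(sprintf("incremental_path: selected %d feature(s) at stop_alpha = %g\n",
              x$selected_size, x$stop_alpha))
  print(x$path)
  invisible(x)
}

#' Compare two candidate panels with the corrected CV test
#'
#' Both panels are evaluated by repeated CV on the identical fold plan;
#' the per-run test-AUC differences (panel A minus panel B) feed the
#' corrected repeated k-fold CV test. Used, e.g., to show that a
#' parsimonious panel performs comparably to a much larger published
#' panel.
#'
#' @param X Feature matrix containing both panels' features.
#' @param y Binary outcome.
#' @param panel_a,panel_b Character vectors of feature names (non-empty;
#'   overlap allowed).
#' @param settings A [cv_settings()].
#' @return List with `test` (a `corrected_cv_test`), `cv_a`, `cv_b`.
#' @export
compare_panels <- function(X, y, panel_a, panel_b,
                           settings = cv_settings()) {
  X <- as_feature_matrix(X)
  panel_a <- as.character(panel_a); panel_b <- as.character(panel_b)
  if (length(panel_a) == 0L || length(panel_b) == 0L) {
    stop("panels must be non-empty")
  }
  missing <- setdiff(c(panel_a, panel_b), colnames(X))
  if (length(missing) > 0L) {
    stop("panel features absent from X: ", paste(missing, collapse = ", "))
  }
  folds <- make_fold_plan(y, settings)
  cv_a <- repeated_cv(X[, panel_a, drop = FALSE], y, settings, folds)
  cv_b <- repeated_cv(X[, panel_b, drop = FALSE], y, settings, folds)
  d <- cv_a$runs$test_auc - cv_b$runs$test_auc
  list(test = corrected_cv_ttest(d, k = settings$k, r = settings$r),
       cv_a = cv_a, cv_b = cv_b)
}
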
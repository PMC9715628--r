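#' Cross-validation settings
#'
#' Bundles the design of the repeated cross-validation: `k` folds,
#' `r` repeats, the hyperparameter grid searched by ROC AUC, the tuning
#' mode, and the master seed. The default grid is alpha in 0.1..1.0 by
#' 0.1 and lambda log-spaced from 1e-4 to 10.
#'
#' @param k Number of folds (default 10).
#' @param r Number of repeats (default 10).
#' @param grid List with numeric vectors `alpha` and `lambda`.
#' @param tuning `"nested"` (default): hyperparameters chosen per outer
#'   run by an inner `inner_k`-fold grid search on the (upsampled)
#'   training fold, avoiding optimistic bias. `"none"`: the first grid
#'   entry is used everywhere (no tuning).
#' @param inner_k Inner folds for nested tuning (default 5).
#' @param seed Master seed; spawns per-repeat and per-run child seeds so
#'   the whole design is reproducible.
#' @return A list of class `cv_settings`.
#' @export
cv_settings <- function(k = 10, r = 10,
                        grid = list(alpha = seq(0.1, 1, by = 0.1),
                                    lambda = 10^seq(-4, 1, length.out = 30)),
                        tuning = c("nested", "none"),
                        inner_k = 5, seed = 1) {
  tuning <- match.arg(tuning)
  stopifnot(k >= 2, r >= 1, inner_k >= 2,
            is.numeric(grid$alpha), is.numeric(grid$lambda))
  structure(list(k = as.integer(k), r = as.integer(r), grid = grid,
                 tuning = tuning, inner_k = as.integer(inner_k),
                 seed = as.integer(seed)),
            class = "cv_settings")
}

#' Stratified fold assignment
#'
#' Assigns each sample to one of `k` folds such that per-fold case counts
#' differ by at most one and total fold sizes differ by at most one.
#' Cases are dealt round-robin over a random fold order; controls are
#' then dealt starting from the folds that are currently smallest, which
#' keeps both constraints simultaneously.
#'
#' @param labels Binary vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  if (is.logical(labels)) labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (min(n1, n0) < k) {
    stop(sprintf("each class must have at least k = %d members (have %d/%d)",
                 k, n1, n0))
  }
  set.seed(seed)
  fold <- integer(length(labels))
  case_order <- sample(which(labels == 1))
  fold[case_order] <- rep_len(sample(k), n1)
  # controls fill up the currently smallest folds first
  counts <- tabulate(fold[fold > 0L], nbins = k)
  fill_order <- order(counts, sample(k))  # random tie-break
  ctrl_order <- sample(which(labels == 0))
  fold[ctrl_order] <- rep_len(fill_order, n0)
  fold
}

#' Upsample the minority class of a training fold
#'
#' Returns the training indices augmented with minority-class members
#' drawn with replacement until both classes have the same frequency.
#' Majority members are untouched; an already balanced fold is returned
#' unchanged. Only training members are ever drawn from, so the held-out
#' fold cannot leak in.
#'
#' @param train_idx Integer indices (or ids) of the training samples.
#' @param labels Binary labels for the full cohort, indexable by
#'   `train_idx`.
#' @param seed Integer seed.
#' @return Index multiset (original training indices plus resampled
#'   minority extras).
#' @export
upsample_minority <- function(train_idx, labels, seed = 1) {
  y <- labels[train_idx]
  if (is.logical(y)) y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L) {
    stop("training fold contains a single class; cannot upsample")
  }
  if (n1 == n0) return(train_idx)
  minority <- if (n1 < n0) train_idx[y == 1] else train_idx[y == 0]
  n_extra <- abs(n0 - n1)
  set.seed(seed)
  extra <- minority[sample.int(length(minority), n_extra, replace = TRUE)]
  c(train_idx, extra)
}

#' Repeated stratified k-fold cross-validation of an elastic-net model
#'
#' The workhorse evaluation loop: for each of `r` repeats the samples are
#' split into `k` stratified folds; for each fold the training portion is
#' minority-upsampled, hyperparameters are grid-searched by inner-CV ROC
#' AUC (per the tuning mode), the model is fit on the upsampled training
#' fold (standardizing with its statistics only), and the held-out fold
#' is scored. Nothing from a held-out fold ever enters upsampling,
#' standardization, or tuning.
#'
#' @param X Feature matrix (samples x features, named columns).
#' @param y Binary outcome vector.
#' @param settings A [cv_settings()] object.
#' @param folds Optional precomputed fold plan from [make_fold_plan()];
#'   passing the same plan to several calls pairs their per-run metrics
#'   (required for the corrected CV test).
#' @return A `cv_result`: list with `runs` (data frame, one row per
#'   repeat x fold: chosen alpha/lambda, train/test ROC AUC, test PRC
#'   AUC), `predictions` (long data frame of held-out probabilities),
#'   `importances` (runs x features matrix of |standardized
#'   coefficients|), `summary` (aggregate means/SDs and the overfit gap
#'   = mean train AUC - mean test AUC), and the `design`.
#' @export
repeated_cv <- function(X, y, settings = cv_settings(), folds = NULL) {
  X <- as_feature_matrix(X)
  if (is.logical(y)) y <- as.integer(y)
  stopifnot(length(y) == nrow(X), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  if (is.null(folds)) folds <- make_fold_plan(y, settings)
  k <- settings$k; r <- settings$r

  runs <- vector("list", k * r)
  preds <- vector("list", k * r)
  imp <- matrix(NA_real_, nrow = k * r, ncol = ncol(X),
                dimnames = list(NULL, colnames(X)))
  run <- 0L
  for (j in seq_len(r)) {
    fold_j <- folds$assignments[[j]]
    for (i in seq_len(k)) {
      run <- run + 1L
      test_idx <- which(fold_j == i)
      train_idx <- which(fold_j != i)
      run_seed <- folds$run_seeds[run]
      res <- tryCatch(
        cv_single_run(X, y, train_idx, test_idx, settings, run_seed),
        error = function(e) {
          stop(sprintf("repeat %d, fold %d: %s", j, i, conditionMessage(e)),
               call. = FALSE)
        })
      runs[[run]] <- data.frame(
        repeat_ = j, fold = i, alpha = res$alpha, lambda = res$lambda,
        train_auc = res$train_auc, test_auc = res$test_auc,
        test_prc = res$test_prc)
      preds[[run]] <- data.frame(
        repeat_ = j, fold = i, sample = test_idx,
        prob = unname(res$test_prob), label = y[test_idx])
      imp[run, ] <- res$importance
    }
  }
  runs <- do.call(rbind, runs)
  predictions <- do.call(rbind, preds)
  summary <- list(
    mean_test_auc = mean(runs$test_auc), sd_test_auc = stats::sd(runs$test_auc),
    mean_train_auc = mean(runs$train_auc),
    sd_train_auc = stats::sd(runs$train_auc),
    mean_test_prc = mean(runs$test_prc), sd_test_prc = stats::sd(runs$test_prc),
    overfit_gap = mean(runs$train_auc) - mean(runs$test_auc))
  structure(list(design = list(k = k, r = r, seed = settings$seed,
                               grid = settings$grid, tuning = settings$tuning),
                 runs = runs, predictions = predictions,
                 importances = imp, summary = summary),
            class = "cv_result")
}

#' Precompute a shared fold plan
#'
#' Builds the per-repeat stratified fold assignments and the per-run
#' child seeds from the master seed. Evaluating several candidate panels
#' against the same plan makes their per-run metrics pairwise comparable,
#' which the corrected repeated k-fold CV test requires.
#'
#' @param y Binary labels.
#' @param settings A [cv_settings()].
#' @return List with `assignments` (one integer fold vector per repeat)
#'   and `run_seeds` (k*r child seeds).
#' @export
make_fold_plan <- function(y, settings) {
  set.seed(settings$seed)
  repeat_seeds <- sample.int(2^31 - 2, settings$r)
  run_seeds <- sample.int(2^31 - 2, settings$k * settings$r)
  assignments <- lapply(repeat_seeds, function(s) {
    stratified_folds(y, settings$k, seed = s)
  })
  list(assignments = assignments, run_seeds = run_seeds)
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "cv_result: %d x %d-fold CV | test ROC AUC %.3f (SD %.3f) | test PRC AUC %.3f | overfit gap %.3f\n",
    x$design$r, x$design$k, s$mean_test_auc, s$sd_test_auc,
    s$mean_test_prc, s$overfit_gap))
  invisible(x)
}

# one outer CV run: upsample, tune, fit, score
cv_single_run <- function(X, y, train_idx, test_idx, settings, run_seed) {
  up_idx <- upsample_minority(train_idx, y, seed = run_seed)
  X_tr <- X[up_idx, , drop = FALSE]
  y_tr <- y[up_idx]
  hp <- if (settings$tuning == "nested" &&
            (length(settings$grid$alpha) > 1L ||
             length(settings$grid$lambda) > 1L)) {
    tune_grid(X_tr, y_tr, settings$grid, settings$inner_k,
              seed = run_seed + 1L)
  } else {
    list(alpha = settings$grid$alpha[1L], lambda = settings$grid$lambda[1L])
  }
  model <- fit_penalized_logistic(X_tr, y_tr, alpha = hp$alpha,
                                  lambda = hp$lambda, thresh = 1e-8)
  test_prob <- predict_probability(model, X[test_idx, , drop = FALSE])
  train_prob <- predict_probability(model, X[train_idx, , drop = FALSE])
  list(alpha = hp$alpha, lambda = hp$lambda,
       train_auc = roc_auc(train_prob, y[train_idx]),
       test_auc = roc_auc(test_prob, y[test_idx]),
       test_prc = prc_auc(test_prob, y[test_idx]),
       test_prob = test_prob,
       importance = feature_importance(model)[colnames(X)])
}

# inner-CV grid search by ROC AUC; one glmnet path per (alpha, inner fold)
tune_grid <- function(Xs, y, grid, inner_k, seed) {
  lam <- sort(grid$lambda, decreasing = TRUE)
  fold <- stratified_folds(y, inner_k, seed = seed)
  auc <- matrix(0, nrow = length(grid$alpha), ncol = length(lam))
  mu <- colMeans(Xs)
  sds <- apply(Xs, 2L, stats::sd)
  keep <- sds > 0
  Z <- scale(Xs[, keep, drop = FALSE], center = mu[keep], scale = sds[keep])
  excl <- integer(0)
  if (ncol(Z) == 1L) {  # glmnet needs >= 2 columns; pad and penalize out
    Z <- cbind(Z, .pad = 0)
    excl <- 2L
  }
  for (f in seq_len(inner_k)) {
    tr <- fold != f
    for (a in seq_along(grid$alpha)) {
      fit <- glmnet::glmnet(Z[tr, , drop = FALSE], y[tr],
                            family = "binomial", alpha = grid$alpha[a],
                            lambda = lam, standardize = FALSE, thresh = 1e-6,
                            maxit = 3e5, exclude = excl)
      eta <- stats::predict(fit, Z[!tr, , drop = FALSE], s = lam,
                            type = "link")
      auc[a, ] <- auc[a, ] + vapply(seq_along(lam), function(l) {
        roc_auc(eta[, l], y[!tr])
      }, numeric(1))
    }
  }
  best <- which(auc == max(auc), arr.ind = TRUE)
  # deterministic tie-break: strongest penalty, then largest alpha
  best <- best[order(best[, 2L], -best[, 1L]), , drop = FALSE][1L, ]
  list(alpha = grid$alpha[best[1L]], lambda = lam[best[2L]])
}
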
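#' Fit an elastic-net penalized logistic panel model
#'
#' Minimizes the penalized negative log-likelihood
#' \deqn{\frac{1}{n}\sum_i -[y_i \log p_i + (1-y_i)\log(1-p_i)]
#'   + \lambda\left(\alpha \sum_j |\beta_j| +
#'   \frac{1-\alpha}{2}\sum_j \beta_j^2\right)}
#' over features standardized with the training data's means and standard
#' deviations (stored in the model so that predictions on new cohorts use
#' the frozen training standardization, never the new cohort's). The
#' intercept is unpenalized. The optimization is delegated to
#' \pkg{glmnet} with `standardize = FALSE` so the objective above is
#' matched exactly on the pre-standardized design.
#'
#' @param X Numeric matrix (samples x features) with column names.
#' @param y Binary outcome vector (0/1), both classes present.
#' @param alpha L1 mixing fraction in \[0, 1\] (1 = lasso, 0 = ridge).
#' @param lambda Penalty strength, >= 0.
#' @param thresh Convergence threshold on relative objective change passed
#'   to the solver. Default 1e-10 (tight, so repeated CV runs are
#'   reproducible to well below metric resolution).
#' @return An object of class `panel_model`: list with `feature_ids`,
#'   `coefficients` (on the standardized scale), `intercept`, `alpha`,
#'   `lambda`, `means`, `sds`, and `training_meta`.
#' @export
fit_penalized_logistic <- function(X, y, alpha = 0.5, lambda = 0.01,
                                   thresh = 1e-10) {
  X <- as_feature_matrix(X)
  if (is.logical(y)) y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  if (length(unique(y)) < 2L) {
    stop("y contains a single class; both classes are required to fit")
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  if (lambda < 0) stop("lambda must be >= 0")

  mu <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  zero_var <- which(sds == 0 | !is.finite(sds))
  if (length(zero_var) > 0L) {
    stop("zero-variance feature(s): ",
         paste(colnames(X)[zero_var], collapse = ", "))
  }
  Xs <- scale(X, center = mu, scale = sds)

  if (ncol(Xs) == 1L) {
    # glmnet requires >= 2 columns; pad with a duplicate and penalize it out
    fit <- glmnet::glmnet(
      cbind(Xs, .pad = 0), y, family = "binomial", alpha = alpha,
      lambda = lambda, standardize = FALSE, thresh = thresh,
      maxit = 1e6, exclude = 2L)
    beta <- as.numeric(fit$beta)[1L]
  } else {
    fit <- glmnet::glmnet(
      Xs, y, family = "binomial", alpha = alpha, lambda = lambda,
      standardize = FALSE, thresh = thresh, maxit = 1e6)
    beta <- as.numeric(fit$beta[, 1L])
  }

  structure(
    list(feature_ids = colnames(X),
         coefficients = stats::setNames(beta, colnames(X)),
         intercept = as.numeric(fit$a0)[1L],
         alpha = alpha, lambda = lambda,
         means = stats::setNames(as.numeric(mu), colnames(X)),
         sds = stats::setNames(as.numeric(sds), colnames(X)),
         training_meta = list(n = nrow(X), n_cases = sum(y == 1),
                              fitted = format(Sys.time(), "%Y-%m-%d"))),
    class = "panel_model")
}

#' Predict case probabilities from a panel model
#'
#' Applies the frozen model: features are centred and scaled with the
#' standardization stored at training time (the replication contract --
#' new cohorts are never re-standardized), then passed through the
#' logistic link.
#'
#' @param model A `panel_model`.
#' @param X Feature matrix containing at least the model's features (by
#'   column name; extra columns are ignored).
#' @return Numeric vector of probabilities in (0, 1), named by sample if
#'   `X` has rownames.
#' @export
predict_probability <- function(model, X) {
  stopifnot(inherits(model, "panel_model"))
  X <- as_feature_matrix(X)
  missing <- setdiff(model$feature_ids, colnames(X))
  if (length(missing) > 0L) {
    stop("feature column(s) missing from X: ",
         paste(missing, collapse = ", "))
  }
  Xm <- X[, model$feature_ids, drop = FALSE]
  Z <- sweep(sweep(Xm, 2L, model$means[model$feature_ids], "-"),
             2L, model$sds[model$feature_ids], "/")
  eta <- drop(Z %*% model$coefficients[model$feature_ids]) + model$intercept
  stats::setNames(stats::plogis(eta), rownames(X))
}

#' Feature importances of a panel model
#'
#' Importance is the absolute value of the standardized coefficient --
#' scale-free, zero for features the penalty dropped.
#'
#' @param model A `panel_model`.
#' @return Named nonnegative numeric vector, one entry per model feature.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "panel_model"))
  abs(model$coefficients)
}

#' Serialize a panel model to JSON
#'
#' The JSON carries features, coefficients, intercept, alpha, lambda and
#' the training standardization, so a reloaded model reproduces its
#' predictions bit-identically on the same input.
#'
#' @param model A `panel_model`.
#' @param path File path to write.
#' @return `path`, invisibly.
#' @export
write_panel_model <- function(model, path) {
  stopifnot(inherits(model, "panel_model"))
  obj <- list(features = model$feature_ids,
              coefficients = unname(model$coefficients),
              intercept = model$intercept,
              alpha = model$alpha, lambda = model$lambda,
              means = unname(model$means), sds = unname(model$sds),
              training_meta = model$training_meta)
  # 17 significant digits round-trips IEEE doubles exactly, so a reloaded
  # model predicts bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a panel model from JSON
#'
#' @param path File written by [write_panel_model()].
#' @return A `panel_model`.
#' @export
read_panel_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ids <- as.character(obj$features)
  structure(
    list(feature_ids = ids,
         coefficients = stats::setNames(as.numeric(obj$coefficients), ids),
         intercept = as.numeric(obj$intercept),
         alpha = as.numeric(obj$alpha), lambda = as.numeric(obj$lambda),
         means = stats::setNames(as.numeric(obj$means), ids),
         sds = stats::setNames(as.numeric(obj$sds), ids),
         training_meta = obj$training_meta),
    class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat(sprintf(
    "panel_model: %d feature(s) (%d nonzero), alpha = %g, lambda = %g\n",
    length(x$feature_ids), nz, x$alpha, x$lambda))
  invisible(x)
}

# coerce input to a named numeric matrix
as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("X must be a numeric matrix or data frame")
  }
  if (is.null(colnames(X))) {
    colnames(X) <- paste0("feature_", seq_len(ncol(X)))
  }
  if (anyNA(X)) stop("X contains missing values")
  X
}
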
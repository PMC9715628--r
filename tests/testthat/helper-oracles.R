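# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they share no code
# path with the package implementations they check.

# ROC AUC by explicit enumeration of all (case, control) pairs
oracle_roc_auc <- function(scores, labels) {
  cases <- scores[labels == 1]
  ctrls <- scores[labels == 0]
  total <- 0
  for (a in cases) for (b in ctrls) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(cases) * length(ctrls))
}

# average precision by a literal descending-score sweep (ties as blocks)
oracle_avg_precision <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  n_pos <- sum(y == 1)
  ap <- 0; prev_recall <- 0; i <- 1
  while (i <= length(s)) {
    j <- i
    while (j < length(s) && s[j + 1] == s[i]) j <- j + 1
    tp <- sum(y[seq_len(j)] == 1)
    recall <- tp / n_pos
    precision <- tp / j
    ap <- ap + (recall - prev_recall) * precision
    prev_recall <- recall
    i <- j + 1
  }
  ap
}

# Benjamini-Hochberg step-up, written out literally
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) q[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exact product-of-ranks rank product (importance rank 1 = largest)
oracle_rank_product <- function(imp) {
  ranks <- apply(imp, 1, function(v) rank(-v, ties.method = "average"))
  apply(ranks, 1, function(r) prod(r)^(1 / length(r)))
}

# unpenalized logistic ML by Newton-Raphson on a standardized design
oracle_logistic_ml <- function(X, y, tol = 1e-12, max_iter = 100) {
  Z <- cbind(1, scale(X))
  beta <- rep(0, ncol(Z))
  for (i in seq_len(max_iter)) {
    p <- plogis(drop(Z %*% beta))
    W <- p * (1 - p)
    step <- solve(crossprod(Z, Z * W), crossprod(Z, y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# classical pooled-variance two-sample t, textbook form
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t_stat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t_stat, df = nx + ny - 2,
       p = 2 * pt(-abs(t_stat), nx + ny - 2))
}

# small default cohort used by several tests
toy_config <- function(seed, n = 250, ...) {
  sim_config(n_samples = n, n_nasal_cpg = 30, n_blood_cpg = 20,
             n_snp = 10, seed = seed, ...)
}

# fast fixed-hyperparameter CV settings for unit tests
fast_settings <- function(seed, k = 5, r = 2) {
  cv_settings(k = k, r = r, grid = list(alpha = 0.1, lambda = 0.05),
              tuning = "none", seed = seed)
}
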
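#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up BH adjustment with monotonicity enforcement, stable under
#' input reordering (delegates to `stats::p.adjust`).
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values, same length and order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numeric in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' eQTM scan: gene expression against CpG methylation
#'
#' For every (CpG, gene) pair, fits the ordinary least-squares model
#' `expression ~ methylation + covariates` and records the slope,
#' standard error, t and p of the methylation term. BH adjustment is
#' applied within each CpG's gene family (FDR controlled at each CpG
#' level), so q-values are comparable within, not across, CpGs.
#'
#' @param cpg_matrix Samples x CpGs methylation matrix (M-values).
#' @param expression_matrix Samples x genes matrix, log scale.
#' @param covariates Data frame of per-sample covariates (e.g. age, sex,
#'   batch, study center); factors are expanded via `model.matrix`.
#' @return Data frame of association records: `predictor` (CpG),
#'   `response` (gene), `slope`, `se`, `t`, `p`, `q`, `n`, `significant`
#'   (q < 0.05).
#' @export
eqtm_scan <- function(cpg_matrix, expression_matrix, covariates) {
  cpg_matrix <- as_feature_matrix(cpg_matrix)
  expression_matrix <- as_feature_matrix(expression_matrix)
  n <- nrow(cpg_matrix)
  if (nrow(expression_matrix) != n || nrow(covariates) != n) {
    stop("cpg_matrix, expression_matrix and covariates must share samples")
  }
  C <- covariate_design(covariates)
  out <- vector("list", ncol(cpg_matrix))
  for (ci in seq_len(ncol(cpg_matrix))) {
    fits <- ols_scan(cbind(1, x = cpg_matrix[, ci], C),
                     expression_matrix, term = 2L)
    rec <- data.frame(predictor = colnames(cpg_matrix)[ci],
                      response = colnames(expression_matrix),
                      slope = fits$slope, se = fits$se, t = fits$t,
                      p = fits$p, stringsAsFactors = FALSE)
    rec$q <- bh_fdr(rec$p)   # per-CpG family
    rec$n <- n
    out[[ci]] <- rec
  }
  res <- do.call(rbind, out)
  res$significant <- res$q < 0.05
  rownames(res) <- NULL
  res
}

#' MeQTL scan: CpG methylation against SNP dosage
#'
#' For each (SNP, CpG) pair, fits `methylation ~ dosage + covariates` and
#' reports the nominal p-value of the dosage term; pairs are flagged at
#' p < 0.05 without multiplicity adjustment (candidate-SNP design).
#' Monomorphic SNPs are skipped with a warning.
#'
#' @param snp_dosages Samples x SNPs matrix of allele dosages in \[0, 2\].
#' @param cpg_matrix Samples x CpGs methylation matrix (M-values).
#' @param covariates Data frame of per-sample covariates; default
#'   `NULL` fits dosage only.
#' @return Data frame: `predictor` (SNP), `response` (CpG), `slope`,
#'   `se`, `t`, `p`, `n`, `significant` (p < 0.05).
#' @export
meqtl_scan <- function(snp_dosages, cpg_matrix, covariates = NULL) {
  snp_dosages <- as_feature_matrix(snp_dosages)
  cpg_matrix <- as_feature_matrix(cpg_matrix)
  n <- nrow(snp_dosages)
  if (nrow(cpg_matrix) != n) stop("matrices must share samples")
  if (any(snp_dosages < 0 | snp_dosages > 2)) {
    stop("dosages must lie in [0, 2]")
  }
  C <- if (is.null(covariates)) NULL else covariate_design(covariates)
  out <- list()
  for (si in seq_len(ncol(snp_dosages))) {
    g <- snp_dosages[, si]
    if (stats::var(g) == 0) {
      warning("monomorphic SNP skipped: ", colnames(snp_dosages)[si])
      next
    }
    design <- if (is.null(C)) cbind(1, g = g) else cbind(1, g = g, C)
    fits <- ols_scan(design, cpg_matrix, term = 2L)
    out[[length(out) + 1L]] <- data.frame(
      predictor = colnames(snp_dosages)[si],
      response = colnames(cpg_matrix),
      slope = fits$slope, se = fits$se, t = fits$t, p = fits$p, n = n,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) stop("no polymorphic SNPs to test")
  res <- do.call(rbind, out)
  res$significant <- res$p < 0.05
  rownames(res) <- NULL
  res
}

#' Pairwise two-sided Student's t contrasts between groups
#'
#' Pooled-variance (classical Student) two-sided t-tests between the
#' requested group pairs of a stratified methylation vector, with the
#' usual significance tiers (`****` p < 1e-4, `***` < 1e-3, `**` < 0.01,
#' `*` < 0.05, `ns` otherwise). Typical stratifications are the four
#' IgE+/- x symptom+/- groups and the symptom-count (multimorbidity)
#' gradient.
#'
#' @param values Numeric per-sample vector (e.g. one CpG's M-values).
#' @param groups Factor or vector of group labels, same length.
#' @param pairs Optional list of length-2 vectors of group labels to
#'   compare; default all pairs of observed groups.
#' @param var_equal Use the pooled-variance Student's t (default TRUE);
#'   set FALSE for Welch.
#' @return Data frame: `group1`, `group2`, `mean1`, `mean2`, `t`, `df`,
#'   `p`, `tier`.
#' @export
group_contrast <- function(values, groups, pairs = NULL, var_equal = TRUE) {
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length")
  }
  groups <- as.character(groups)
  lev <- unique(groups)
  sizes <- table(groups)
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2L, simplify = FALSE)
  }
  rows <- lapply(pairs, function(pr) {
    if (!all(pr %in% lev)) {
      stop("unknown group(s): ", paste(setdiff(pr, lev), collapse = ", "))
    }
    if (any(sizes[pr] < 2L)) {
      stop("group(s) with fewer than 2 members: ",
           paste(pr[sizes[pr] < 2L], collapse = ", "))
    }
    x <- values[groups == pr[1L]]
    y <- values[groups == pr[2L]]
    tt <- stats::t.test(x, y, var.equal = var_equal)
    data.frame(group1 = pr[1L], group2 = pr[2L],
               mean1 = mean(x), mean2 = mean(y),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, tier = significance_tier(tt$p.value),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

significance_tier <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else
    if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

# expand covariates to a full-rank numeric design (no intercept column)
covariate_design <- function(covariates) {
  covariates <- as.data.frame(covariates)
  mm <- stats::model.matrix(~ ., data = covariates)
  C <- mm[, -1L, drop = FALSE]
  qrC <- qr(cbind(1, C))
  if (qrC$rank < ncol(C) + 1L) {
    aliased <- colnames(cbind(1, C))[qrC$pivot[-seq_len(qrC$rank)]]
    stop("collinear covariate column(s): ", paste(aliased, collapse = ", "))
  }
  C
}

# OLS of each response column on a fixed design; stats for `term`
ols_scan <- function(design, Y, term) {
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("rank-deficient design")
  coefs <- qr.coef(qr_d, Y)
  res <- qr.resid(qr_d, Y)
  df <- nrow(design) - ncol(design)
  sigma2 <- colSums(res^2) / df
  xtx_inv_jj <- chol2inv(qr.R(qr_d))[term, term]
  se <- sqrt(sigma2 * xtx_inv_jj)
  slope <- coefs[term, ]
  t_stat <- slope / se
  p <- 2 * stats::pt(-abs(t_stat), df = df)
  list(slope = unname(slope), se = unname(se), t = unname(t_stat),
       p = unname(p))
}
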
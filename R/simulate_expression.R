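#' Simulate gene expression linked to CpG methylation (eQTM design)
#'
#' Generates a log-scale expression matrix in which each planted
#' (CpG, gene, slope) pair from the ground truth contributes
#' `slope * M` to that gene, on top of per-gene covariate effects
#' (age, sex, and balanced batch/center assignments: 4 batches, 2
#' centers) and Gaussian noise of SD `noise_sd`. All remaining genes
#' are covariates plus noise only, giving a clean null for calibration.
#'
#' @param cohort An `omics_cohort` with a `nasal_meth` layer.
#' @param truth A `synthetic_truth` (its `eqtm_truth` pairs are
#'   planted).
#' @param config The [sim_config()] used (supplies `n_genes`,
#'   `noise_sd`, and the seed; expression uses `seed + 1` so it is
#'   reproducible but independent of the cohort draw).
#' @return List with `expression` (samples x genes matrix) and
#'   `covariates` (data frame: age, sex, batch, center).
#' @export
simulate_expression <- function(cohort, truth, config) {
  stopifnot(inherits(cohort, "omics_cohort"),
            inherits(config, "sim_config"))
  if (!"nasal_meth" %in% names(cohort$layers)) {
    stop("cohort has no nasal methylation layer")
  }
  nasal <- cohort$layers$nasal_meth
  pairs <- truth$eqtm_truth
  unknown <- setdiff(pairs$cpg, colnames(nasal))
  if (length(unknown) > 0L) {
    stop("eQTM truth references unknown CpG(s): ",
         paste(unknown, collapse = ", "))
  }
  set.seed(config$seed + 1L)
  n <- nrow(nasal)
  gene_ids <- union(pairs$gene, sprintf("gene%04d", seq_len(config$n_genes)))
  gene_ids <- gene_ids[seq_len(max(config$n_genes, length(pairs$gene)))]
  p <- length(gene_ids)

  batch <- factor(sample(rep_len(paste0("b", 1:4), n)))
  center <- factor(sample(rep_len(paste0("c", 1:2), n)))
  age <- cohort$phenotype$age
  sex <- cohort$phenotype$sex

  baseline <- stats::rnorm(p, 6, 1)
  age_eff <- stats::rnorm(p, 0, 0.05)
  sex_eff <- stats::rnorm(p, 0, 0.2)
  batch_eff <- matrix(stats::rnorm(4L * p, 0, 0.3), 4L, p)
  center_eff <- matrix(stats::rnorm(2L * p, 0, 0.3), 2L, p)

  expr <- outer(rep(1, n), baseline) +
    outer(age - mean(age), age_eff) + outer(sex, sex_eff) +
    batch_eff[as.integer(batch), , drop = FALSE] +
    center_eff[as.integer(center), , drop = FALSE] +
    matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
  dimnames(expr) <- list(rownames(nasal), gene_ids)
  for (i in seq_len(nrow(pairs))) {
    g <- pairs$gene[i]
    expr[, g] <- expr[, g] + pairs$slope[i] * nasal[, pairs$cpg[i]]
  }
  covariates <- data.frame(age = age, sex = sex, batch = batch,
                           center = center)
  rownames(covariates) <- rownames(nasal)
  list(expression = expr, covariates = covariates)
}

#' Simulate a SNP -> CpG -> disease mediation chain
#'
#' Generates a single-locus chain: dosage `G` from Hardy-Weinberg at
#' `maf`; mediator `M = a G + e`, `e ~ N(0,1)`; binary outcome with
#' `P(Y=1) = logistic(c0 + c_prime G + b M)`, where the intercept `c0`
#' is solved numerically so the marginal prevalence matches
#' `prevalence`. The returned `prop_mediated_true` is the
#' product-of-coefficients proportion `a b / (a b + c_prime)` -- the
#' closed form the generating slopes imply on the linear surrogate
#' scale.
#'
#' @param n Sample size.
#' @param maf Minor-allele frequency in (0, 0.5].
#' @param a,b,c_prime Generating slopes (SNP->CpG, CpG->outcome
#'   log-odds, direct log-odds).
#' @param seed Integer seed.
#' @param prevalence Target marginal outcome prevalence (default 0.3).
#' @return List with `G`, `M`, `Y`, `prop_mediated_true`, and the
#'   solved intercept `c0`.
#' @export
simulate_mediation_chain <- function(n, maf, a, b, c_prime, seed = 1,
                                     prevalence = 0.3) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be in (0, 1)")
  }
  set.seed(seed)
  hw <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  G <- sample(0:2, n, replace = TRUE, prob = hw)
  M <- a * G + stats::rnorm(n)
  eta0 <- c_prime * G + b * M
  c0 <- stats::uniroot(function(c0) mean(stats::plogis(c0 + eta0)) - prevalence,
                       interval = c(-30, 30))$root
  Y <- stats::rbinom(n, 1L, stats::plogis(c0 + eta0))
  list(G = G, M = M, Y = Y,
       prop_mediated_true = mediated_proportion(a, b, c_prime), c0 = c0)
}
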
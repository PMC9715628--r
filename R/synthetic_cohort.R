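#' Configuration of a synthetic multi-omics cohort
#'
#' Defines the generative model: a binary allergic-disease status with
#' prevalence `prevalence`, a small set of causal nasal CpGs whose
#' M-values are shifted downward in cases by `delta` standard deviations
#' (equicorrelated at `rho`), attenuated homologous shifts in blood,
#' weak SNP effects feeding a polygenic risk score, environmental
#' binaries with small odds effects, and a symptom-count gradient among
#' cases (methylation decreases with the number of allergic symptoms).
#'
#' Defaults mirror the discovery-cohort conditions: n = 348 samples,
#' prevalence 0.193, 134 nasal and 219 blood candidate CpGs, 101
#' candidate SNPs, 5 environmental/perinatal binaries, 3 causal CpGs
#' with delta = 1.1 and rho = 0.5, and a strongly attenuated blood
#' signal (attenuation 0.1).
#'
#' @param n_samples Cohort size.
#' @param prevalence Case fraction in (0, 1).
#' @param n_nasal_cpg,n_blood_cpg,n_snp,n_env Feature counts per layer.
#' @param n_causal Number of causal nasal CpGs (<= n_nasal_cpg).
#' @param delta Standardized case-control M-value shift at causal CpGs
#'   (case mean lower), >= 0.
#' @param rho Pairwise correlation among causal CpGs, in \[0, 1).
#' @param blood_attenuation Multiplier in \[0, 1\] applied to `delta` for
#'   the blood homolog CpGs.
#' @param maf_range Interval of minor-allele frequencies, within (0, 0.5].
#' @param snp_logor_range Interval of per-allele log-odds effects.
#' @param n_genes,eqtm_slope,noise_sd Expression-link parameters for
#'   [simulate_expression()].
#' @param mediation List with slopes `a` (SNP -> CpG), `b` (CpG ->
#'   outcome log-odds) and `c_prime` (direct log-odds).
#' @param seed Integer seed; identical configs give bit-identical
#'   cohorts.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 348, prevalence = 0.193,
                       n_nasal_cpg = 134, n_blood_cpg = 219,
                       n_snp = 101, n_env = 5, n_causal = 3,
                       delta = 1.1, rho = 0.5, blood_attenuation = 0.1,
                       maf_range = c(0.1, 0.5),
                       snp_logor_range = c(0.02, 0.15),
                       n_genes = 200, eqtm_slope = 1, noise_sd = 0.5,
                       mediation = list(a = 0.3, b = 0.5, c_prime = 0.5),
                       seed = 1) {
  cfg <- list(n_samples = as.integer(n_samples), prevalence = prevalence,
              n_nasal_cpg = as.integer(n_nasal_cpg),
              n_blood_cpg = as.integer(n_blood_cpg),
              n_snp = as.integer(n_snp), n_env = as.integer(n_env),
              n_causal = as.integer(n_causal), delta = delta, rho = rho,
              blood_attenuation = blood_attenuation,
              maf_range = maf_range, snp_logor_range = snp_logor_range,
              n_genes = as.integer(n_genes), eqtm_slope = eqtm_slope,
              noise_sd = noise_sd, mediation = mediation,
              seed = as.integer(seed))
  with(cfg, {
    if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0,1)")
    if (delta < 0) stop("delta must be >= 0")
    if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
    if (blood_attenuation < 0 || blood_attenuation > 1) {
      stop("blood_attenuation must be in [0, 1]")
    }
    if (maf_range[1] <= 0 || maf_range[2] > 0.5) {
      stop("maf_range must lie within (0, 0.5]")
    }
    if (any(c(n_samples, n_nasal_cpg, n_blood_cpg, n_snp, n_env,
              n_causal, n_genes) < 1L)) {
      stop("all counts must be >= 1")
    }
    if (n_causal > n_nasal_cpg) stop("n_causal must be <= n_nasal_cpg")
    if (prevalence * n_samples < 2) {
      stop("infeasible config: expected case count below 2")
    }
  })
  structure(cfg, class = "sim_config")
}

# fixed generator constants (documented modeling choices)
SYMPTOM_PROBS_CASE <- c(0.6, 0.3, 0.1)        # P(symptom_count = 1,2,3 | case)
SYMPTOM_GRADIENT <- 0.15                      # extra shift (x delta) per symptom
CONTROL_IGE_PROB <- 0.34                      # P(IgE+ | control)
CONTROL_IGE_SHIFT <- 0.15                     # IgE+ control shift (x delta)
CONTROL_SYMPTOM_PROBS <- c(0.8, 0.14, 0.05, 0.01)  # IgE- controls, count 0..3

#' Simulate a multi-omics cohort with planted ground truth
#'
#' Status is generated first (Bernoulli at the configured prevalence);
#' features are drawn conditional on status, matching the group-wise
#' distributions the analysis is designed to detect. Causal nasal CpGs
#' are class-conditional equicorrelated Gaussians on the M-scale with
#' case means shifted down by `delta` (plus a centred symptom-count
#' gradient among cases and a centred IgE shift among controls, so the
#' marginal case-control shift stays exactly `delta`). Blood homologs
#' get `delta * blood_attenuation`. SNP dosages follow Hardy-Weinberg
#' with class-conditional tilting by their log-odds effects, and a
#' weighted-dosage polygenic risk score column is appended.
#'
#' @param config A [sim_config()].
#' @return A list: `cohort` (an `omics_cohort`) and `truth` (a
#'   `synthetic_truth` with the causal CpG ids, per-CpG shifts, eQTM
#'   pairs, and mediation slopes with the true mediated proportion).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  pi0 <- config$prevalence
  sample_ids <- sprintf("S%04d", seq_len(n))

  allergy <- stats::rbinom(n, 1L, pi0)
  cases <- allergy == 1L
  # phenotype logic: disease = symptoms AND IgE sensitization
  symptom_count <- integer(n)
  ige <- integer(n)
  ige[cases] <- 1L
  symptom_count[cases] <- sample(1:3, sum(cases), replace = TRUE,
                                 prob = SYMPTOM_PROBS_CASE)
  ige[!cases] <- stats::rbinom(sum(!cases), 1L, CONTROL_IGE_PROB)
  ctrl_ige_neg <- !cases & ige == 0L
  symptom_count[ctrl_ige_neg] <- sample(0:3, sum(ctrl_ige_neg),
                                        replace = TRUE,
                                        prob = CONTROL_SYMPTOM_PROBS)
  age <- stats::rnorm(n, 16.3, 0.2)
  sex <- stats::rbinom(n, 1L, 0.5)

  # --- nasal methylation layer (M-scale) ---
  mu_nasal <- stats::runif(config$n_nasal_cpg, -2, 2)
  nasal_ids <- sprintf("ncg%05d", seq_len(config$n_nasal_cpg))
  causal_idx <- sort(sample.int(config$n_nasal_cpg, config$n_causal))
  nasal <- matrix(stats::rnorm(n * config$n_nasal_cpg), n,
                  dimnames = list(sample_ids, nasal_ids))
  nasal <- sweep(nasal, 2L, mu_nasal, "+")
  shift <- methylation_shift(allergy, symptom_count, ige, config$delta)
  nasal[, causal_idx] <- sweep(
    correlated_noise(n, config$n_causal, config$rho), 2L,
    mu_nasal[causal_idx], "+") + shift
  colnames(nasal) <- nasal_ids

  # --- blood methylation layer: attenuated homolog shifts ---
  mu_blood <- stats::runif(config$n_blood_cpg, -2, 2)
  blood_ids <- sprintf("bcg%05d", seq_len(config$n_blood_cpg))
  blood <- matrix(stats::rnorm(n * config$n_blood_cpg), n,
                  dimnames = list(sample_ids, blood_ids))
  blood <- sweep(blood, 2L, mu_blood, "+")
  n_hom <- min(config$n_causal, config$n_blood_cpg)
  blood_shift <- -config$delta * config$blood_attenuation * allergy
  blood[, seq_len(n_hom)] <- blood[, seq_len(n_hom)] + blood_shift

  # --- genetics: HW dosages tilted by class, plus a PRS column ---
  mafs <- stats::runif(config$n_snp, config$maf_range[1], config$maf_range[2])
  logors <- stats::runif(config$n_snp, config$snp_logor_range[1],
                         config$snp_logor_range[2])
  c0 <- stats::qlogis(pi0)
  G <- matrix(0L, n, config$n_snp,
              dimnames = list(sample_ids,
                              sprintf("snp%04d", seq_len(config$n_snp))))
  for (s in seq_len(config$n_snp)) {
    hw <- c((1 - mafs[s])^2, 2 * mafs[s] * (1 - mafs[s]), mafs[s]^2)
    lik1 <- stats::plogis(c0 + logors[s] * 0:2)
    p_case <- hw * lik1 / sum(hw * lik1)
    p_ctrl <- hw * (1 - lik1) / sum(hw * (1 - lik1))
    G[cases, s] <- sample(0:2, sum(cases), replace = TRUE, prob = p_case)
    G[!cases, s] <- sample(0:2, sum(!cases), replace = TRUE, prob = p_ctrl)
  }
  genetics <- cbind(G, prs_allergy = drop(G %*% logors))

  # --- environmental / perinatal binaries with small odds effects ---
  env_names <- c("low_birth_weight", "breastfeeding", "pets_pregnancy",
                 "maternal_smoking", "older_siblings")
  if (config$n_env > length(env_names)) {
    env_names <- c(env_names,
                   sprintf("env%02d", seq_len(config$n_env - length(env_names))))
  }
  env_names <- env_names[seq_len(config$n_env)]
  p_env <- stats::runif(config$n_env, 0.1, 0.4)
  lor_env <- stats::runif(config$n_env, -0.3, 0.3)
  E <- matrix(0L, n, config$n_env, dimnames = list(sample_ids, env_names))
  for (e in seq_len(config$n_env)) {
    pe1 <- p_env[e] * stats::plogis(c0 + lor_env[e])
    pe0 <- (1 - p_env[e]) * stats::plogis(c0)
    p_case <- pe1 / (pe1 + pe0)
    qe1 <- p_env[e] * (1 - stats::plogis(c0 + lor_env[e]))
    qe0 <- (1 - p_env[e]) * (1 - stats::plogis(c0))
    p_ctrl <- qe1 / (qe1 + qe0)
    E[, e] <- stats::rbinom(n, 1L, ifelse(cases, p_case, p_ctrl))
  }
  n_perinatal <- min(2L, config$n_env)

  phenotype <- data.frame(sample_id = sample_ids, allergy = allergy,
                          ige_sensitized = ige,
                          symptom_count = symptom_count,
                          age = age, sex = sex, stringsAsFactors = FALSE)
  layers <- list(
    age_sex = cbind(age = age, sex = sex),
    perinatal = E[, seq_len(n_perinatal), drop = FALSE],
    genetics = genetics, blood_meth = blood, nasal_meth = nasal)
  if (config$n_env > n_perinatal) {
    layers$environment <- E[, (n_perinatal + 1L):config$n_env, drop = FALSE]
  }
  layers <- layers[intersect(
    c("age_sex", "perinatal", "environment", "genetics",
      "blood_meth", "nasal_meth"), names(layers))]
  for (nm in names(layers)) rownames(layers[[nm]]) <- sample_ids

  cohort <- omics_cohort(phenotype, layers,
                         value_scale = c(blood_meth = "M", nasal_meth = "M"))
  med <- config$mediation
  truth <- structure(list(
    causal_cpg_ids = nasal_ids[causal_idx],
    delta_per_cpg = stats::setNames(rep(config$delta, config$n_causal),
                                    nasal_ids[causal_idx]),
    eqtm_truth = data.frame(
      cpg = nasal_ids[causal_idx],
      gene = sprintf("gene%04d", seq_len(config$n_causal)),
      slope = config$eqtm_slope, stringsAsFactors = FALSE),
    mediation_truth = list(
      a = med$a, b = med$b, c_prime = med$c_prime,
      prop_mediated_true = mediated_proportion(med$a, med$b, med$c_prime)),
    seed = config$seed), class = "synthetic_truth")
  list(cohort = cohort, truth = truth)
}

# case/control mean shift at causal CpGs, centred so the marginal
# case-control difference equals exactly delta
methylation_shift <- function(allergy, symptom_count, ige, delta) {
  mean_sc_case <- sum(1:3 * SYMPTOM_PROBS_CASE)
  shift <- numeric(length(allergy))
  cases <- allergy == 1L
  shift[cases] <- -delta -
    SYMPTOM_GRADIENT * delta * (symptom_count[cases] - mean_sc_case)
  shift[!cases] <- -CONTROL_IGE_SHIFT * delta *
    (ige[!cases] - CONTROL_IGE_PROB)
  shift
}

# n x p equicorrelated standard Gaussian noise
correlated_noise <- function(n, p, rho) {
  if (p == 1L) return(matrix(stats::rnorm(n), n, 1L))
  sigma <- matrix(rho, p, p); diag(sigma) <- 1
  matrix(stats::rnorm(n * p), n, p) %*% chol(sigma)
}

# true mediated proportion on the product-of-coefficients scale
mediated_proportion <- function(a, b, c_prime) {
  ind <- a * b
  tot <- ind + c_prime
  if (tot == 0) return(NA_real_)
  ind / tot
}

#' Construct and validate a multi-omics cohort container
#'
#' The universal pipeline input: one phenotype table plus named feature
#' layers sharing the same samples in the same order. Validation
#' enforces the phenotype logic (every case is IgE-sensitized with at
#' least one symptom), complete data, and beta-range checks for layers
#' declared on the beta scale.
#'
#' @param phenotype Data frame with columns `sample_id`, `allergy`,
#'   `ige_sensitized`, `symptom_count`, `age`, `sex`.
#' @param layers Named list of numeric matrices (samples x features).
#' @param value_scale Named character vector mapping methylation layer
#'   names to `"beta"` or `"M"`.
#' @return An object of class `omics_cohort`.
#' @export
omics_cohort <- function(phenotype, layers, value_scale = character(0)) {
  req <- c("sample_id", "allergy", "ige_sensitized", "symptom_count",
           "age", "sex")
  if (!all(req %in% names(phenotype))) {
    stop("phenotype must contain columns: ", paste(req, collapse = ", "))
  }
  if (anyNA(phenotype)) stop("phenotype contains missing values")
  if (anyDuplicated(phenotype$sample_id)) {
    stop("duplicated sample ids in phenotype")
  }
  bad <- phenotype$allergy == 1 &
    (phenotype$ige_sensitized != 1 | phenotype$symptom_count < 1)
  if (any(bad)) {
    stop("phenotype logic violated (case without IgE or symptoms): ",
         paste(phenotype$sample_id[bad], collapse = ", "))
  }
  if (is.null(names(layers)) || any(names(layers) == "")) {
    stop("layers must be named")
  }
  for (nm in names(layers)) {
    m <- layers[[nm]]
    if (!is.matrix(m) || !is.numeric(m)) {
      stop(sprintf("layer '%s' must be a numeric matrix", nm))
    }
    if (nrow(m) != nrow(phenotype)) {
      stop(sprintf("layer '%s' has %d rows; phenotype has %d",
                   nm, nrow(m), nrow(phenotype)))
    }
    if (!is.null(rownames(m)) &&
        !identical(rownames(m), phenotype$sample_id)) {
      stop(sprintf("layer '%s' sample order differs from phenotype", nm))
    }
    if (anyNA(m)) stop(sprintf("layer '%s' contains missing values", nm))
    if (identical(unname(value_scale[nm]), "beta") &&
        (any(m <= 0) || any(m >= 1))) {
      stop(sprintf("layer '%s' declared beta-scale but has values outside (0,1)",
                   nm))
    }
  }
  structure(list(sample_ids = phenotype$sample_id, phenotype = phenotype,
                 layers = layers, value_scale = value_scale),
            class = "omics_cohort")
}

#' @export
print.omics_cohort <- function(x, ...) {
  cat(sprintf("omics_cohort: %d samples (%d cases), %d layer(s)\n",
              length(x$sample_ids), sum(x$phenotype$allergy),
              length(x$layers)))
  for (nm in names(x$layers)) {
    cat(sprintf("  %-12s %d feature(s)\n", nm, ncol(x$layers[[nm]])))
  }
  invisible(x)
}

#' Bind selected cohort layers into one feature matrix
#'
#' @param cohort An `omics_cohort`.
#' @param layers Character vector of layer names (default all).
#' @return Numeric matrix, samples x features.
#' @export
cohort_features <- function(cohort, layers = names(cohort$layers)) {
  stopifnot(inherits(cohort, "omics_cohort"))
  missing <- setdiff(layers, names(cohort$layers))
  if (length(missing) > 0L) {
    stop("unknown layer(s): ", paste(missing, collapse = ", "))
  }
  do.call(cbind, cohort$layers[layers])
}
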
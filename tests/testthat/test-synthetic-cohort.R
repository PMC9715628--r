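test_that("sim_config validates its parameter space", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(prevalence = 0), "prevalence")
  expect_error(sim_config(prevalence = 1.2), "prevalence")
  expect_error(sim_config(delta = -1), "delta")
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(blood_attenuation = 2), "attenuation")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf")
  expect_error(sim_config(n_causal = 200, n_nasal_cpg = 100), "n_causal")
  expect_error(sim_config(n_samples = 5, prevalence = 0.1), "infeasible")
})

test_that("the generator is bit-reproducible and seed-sensitive", {
  a <- simulate_cohort(toy_config(42))
  b <- simulate_cohort(toy_config(42))
  expect_identical(a$cohort$layers, b$cohort$layers)
  expect_identical(a$cohort$phenotype, b$cohort$phenotype)
  expect_identical(a$truth$causal_cpg_ids, b$truth$causal_cpg_ids)
  c <- simulate_cohort(toy_config(43))
  expect_false(identical(a$cohort$layers$nasal_meth,
                         c$cohort$layers$nasal_meth))
})

test_that("cohort dimensions and case fraction honor the config", {
  cfg <- sim_config(n_samples = 348, prevalence = 0.193, seed = 10)
  sim <- simulate_cohort(cfg)
  ph <- sim$cohort$phenotype
  expect_equal(nrow(ph), 348)
  expect_equal(ncol(sim$cohort$layers$nasal_meth), 134)
  expect_equal(ncol(sim$cohort$layers$blood_meth), 219)
  expect_equal(ncol(sim$cohort$layers$genetics), 102)  # 101 SNPs + PRS
  # binomial 99.9% interval for the realized case count
  ci <- qbinom(c(5e-4, 1 - 5e-4), 348, 0.193)
  expect_gte(sum(ph$allergy), ci[1])
  expect_lte(sum(ph$allergy), ci[2])
  # phenotype logic: every case is IgE-sensitized with >= 1 symptom
  expect_true(all(ph$ige_sensitized[ph$allergy == 1] == 1))
  expect_true(all(ph$symptom_count[ph$allergy == 1] >= 1))
  # dosages are valid and the PRS is the log-OR-weighted dosage sum
  G <- sim$cohort$layers$genetics[, 1:101]
  expect_true(all(G %in% 0:2))
})

test_that("causal CpGs carry the configured standardized shift", {
  cfg <- sim_config(n_samples = 5000, prevalence = 0.3, seed = 77,
                    n_nasal_cpg = 20, n_blood_cpg = 10, n_snp = 5)
  sim <- simulate_cohort(cfg)
  y <- sim$cohort$phenotype$allergy
  nasal <- sim$cohort$layers$nasal_meth
  for (cg in sim$truth$causal_cpg_ids) {
    d_std <- (mean(nasal[y == 0, cg]) - mean(nasal[y == 1, cg])) /
      sd(nasal[, cg])
    # cases shifted DOWN by ~delta units of the unit noise SD; the
    # pooled-SD denominator absorbs part of the shift, so allow 0.15
    expect_lt(abs((mean(nasal[y == 0, cg]) - mean(nasal[y == 1, cg])) - 1.1),
              0.1)
    expect_gt(d_std, 0)
  }
  # non-causal CpGs show no systematic shift
  noise <- setdiff(colnames(nasal), sim$truth$causal_cpg_ids)[1:5]
  for (cg in noise) {
    expect_lt(abs(mean(nasal[y == 0, cg]) - mean(nasal[y == 1, cg])), 0.12)
  }
})

test_that("causal CpG pairs are correlated at approximately rho", {
  cfg <- sim_config(n_samples = 6000, prevalence = 0.3, rho = 0.5,
                    n_nasal_cpg = 10, n_blood_cpg = 5, n_snp = 5, seed = 5)
  sim <- simulate_cohort(cfg)
  y <- sim$cohort$phenotype$allergy
  M <- sim$cohort$layers$nasal_meth[y == 0, sim$truth$causal_cpg_ids]
  cors <- cor(M)[upper.tri(diag(3))]
  expect_true(all(abs(cors - 0.5) < 0.06))
})

test_that("a single causal feature attains its analytic Gaussian AUC", {
  # two Gaussians separated by d SDs give AUC = Phi(d / sqrt(2))
  cfg <- sim_config(n_samples = 5000, prevalence = 0.3, seed = 31,
                    n_nasal_cpg = 10, n_blood_cpg = 5, n_snp = 5,
                    n_causal = 1, rho = 0)
  sim <- simulate_cohort(cfg)
  y <- sim$cohort$phenotype$allergy
  x <- sim$cohort$layers$nasal_meth[, sim$truth$causal_cpg_ids]
  auc <- roc_auc(-x, y)  # cases are shifted down
  expect_lt(abs(auc - pnorm(1.1 / sqrt(2))), 0.02)
})

test_that("blood homologs carry the attenuated shift", {
  cfg <- sim_config(n_samples = 8000, prevalence = 0.3, seed = 88,
                    n_nasal_cpg = 10, n_blood_cpg = 6, n_snp = 5)
  sim <- simulate_cohort(cfg)
  y <- sim$cohort$phenotype$allergy
  blood <- sim$cohort$layers$blood_meth
  d <- mean(blood[y == 0, 1]) - mean(blood[y == 1, 1])
  expect_lt(abs(d - 1.1 * 0.1), 0.05)  # attenuation 0.1
})

test_that("delta = 0 removes the case-control methylation signal", {
  cfg <- toy_config(61, n = 4000, delta = 0)
  sim <- simulate_cohort(cfg)
  y <- sim$cohort$phenotype$allergy
  nasal <- sim$cohort$layers$nasal_meth
  for (cg in sim$truth$causal_cpg_ids) {
    d <- mean(nasal[y == 0, cg]) - mean(nasal[y == 1, cg])
    expect_lt(abs(d), 0.12)
  }
})

test_that("cases show a symptom-count methylation gradient", {
  cfg <- sim_config(n_samples = 12000, prevalence = 0.4, seed = 14,
                    n_nasal_cpg = 10, n_blood_cpg = 5, n_snp = 5)
  sim <- simulate_cohort(cfg)
  ph <- sim$cohort$phenotype
  cg <- sim$truth$causal_cpg_ids[1]
  m <- sim$cohort$layers$nasal_meth[, cg]
  means <- tapply(m[ph$allergy == 1], ph$symptom_count[ph$allergy == 1], mean)
  expect_true(all(diff(means[as.character(1:3)]) < 0))
})

test_that("omics_cohort validation catches malformed inputs", {
  sim <- simulate_cohort(toy_config(9, n = 60))
  ph <- sim$cohort$phenotype
  layers <- sim$cohort$layers
  expect_s3_class(omics_cohort(ph, layers), "omics_cohort")
  bad_ph <- ph; bad_ph$ige_sensitized[bad_ph$allergy == 1][1] <- 0
  expect_error(omics_cohort(bad_ph, layers), "logic")
  short <- layers; short$nasal_meth <- short$nasal_meth[-1, ]
  expect_error(omics_cohort(ph, short), "rows")
  nas <- layers; nas$nasal_meth[2, 3] <- NA
  expect_error(omics_cohort(ph, nas), "missing")
  beta_bad <- layers
  expect_error(
    omics_cohort(ph, beta_bad, value_scale = c(nasal_meth = "beta")),
    "beta")
  expect_error(cohort_features(sim$cohort, "no_such_layer"), "no_such_layer")
  both <- cohort_features(sim$cohort, c("nasal_meth", "blood_meth"))
  expect_equal(ncol(both), 50)
})
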
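test_that("bh_fdr reproduces hand-computed adjustments", {
  # classic worked example
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(bh_fdr(p), c(0.04, 0.04, 0.04, 0.04))
  p2 <- c(0.005, 0.04, 0.8)
  expect_equal(bh_fdr(p2), c(0.015, 0.06, 0.8))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.1, NA)), "\\[0, 1\\]")
})

test_that("bh_fdr matches the literal step-up oracle on random inputs", {
  set.seed(17)
  for (i in 1:20) {
    p <- round(runif(sample(2:12, 1)), 3)
    expect_equal(bh_fdr(p), oracle_bh(p))
  }
  # order equivariance
  p <- runif(9)
  o <- sample(9)
  expect_equal(bh_fdr(p)[o], bh_fdr(p[o]))
})

test_that("eqtm_scan recovers planted pairs and keeps the null clean", {
  cfg <- toy_config(25, n = 300, n_genes = 30)
  sim <- simulate_cohort(cfg)
  ex <- simulate_expression(sim$cohort, sim$truth, cfg)
  res <- eqtm_scan(sim$cohort$layers$nasal_meth[, sim$truth$causal_cpg_ids],
                   ex$expression, ex$covariates)
  expect_equal(nrow(res), 3 * 30)
  key <- paste(res$predictor, res$response)
  truth_key <- paste(sim$truth$eqtm_truth$cpg, sim$truth$eqtm_truth$gene)
  planted <- res[match(truth_key, key), ]
  expect_true(all(planted$significant))
  expect_true(all(abs(planted$slope - sim$truth$eqtm_truth$slope) < 0.2))
  # genes carrying no planted CpG signal stay null-calibrated; pairs of
  # a causal CpG with another causal CpG's gene are excluded because the
  # causal CpGs are mutually correlated (rho), making those real
  null_genes <- !res$response %in% sim$truth$eqtm_truth$gene
  expect_lte(sum(res$significant[null_genes]), 2)
  # q-values are BH within each CpG family
  one <- res[res$predictor == sim$truth$causal_cpg_ids[1], ]
  expect_equal(one$q, bh_fdr(one$p))
})

test_that("eqtm_scan agrees with lm on a single pair", {
  cfg <- toy_config(26, n = 150, n_genes = 10)
  sim <- simulate_cohort(cfg)
  ex <- simulate_expression(sim$cohort, sim$truth, cfg)
  cg <- sim$truth$causal_cpg_ids[1]
  gene <- colnames(ex$expression)[5]
  res <- eqtm_scan(sim$cohort$layers$nasal_meth[, cg, drop = FALSE],
                   ex$expression[, gene, drop = FALSE], ex$covariates)
  fit <- lm(ex$expression[, gene] ~ sim$cohort$layers$nasal_meth[, cg] +
              age + sex + batch + center, data = ex$covariates)
  sm <- summary(fit)$coefficients[2, ]
  expect_equal(res$slope, unname(sm[1]), tolerance = 1e-10)
  expect_equal(res$se, unname(sm[2]), tolerance = 1e-10)
  expect_equal(res$p, unname(sm[4]), tolerance = 1e-10)
})

test_that("collinear covariates are rejected by name", {
  cfg <- toy_config(27, n = 80, n_genes = 5)
  sim <- simulate_cohort(cfg)
  ex <- simulate_expression(sim$cohort, sim$truth, cfg)
  cov2 <- ex$covariates
  cov2$age_copy <- cov2$age
  expect_error(
    eqtm_scan(sim$cohort$layers$nasal_meth[, 1, drop = FALSE],
              ex$expression[, 1, drop = FALSE], cov2),
    "age_copy")
})

test_that("meqtl_scan flags a real chain and skips monomorphic SNPs", {
  ch <- simulate_mediation_chain(800, maf = 0.3, a = 0.4, b = 0.5,
                                 c_prime = 0.5, seed = 11)
  snps <- cbind(rs_live = ch$G, rs_dead = rep(1, 800))
  cpgs <- cbind(cg_target = ch$M)
  expect_warning(res <- meqtl_scan(snps, cpgs), "rs_dead")
  expect_equal(nrow(res), 1)
  expect_true(res$significant)
  expect_lt(abs(res$slope - 0.4), 0.15)
  expect_error(meqtl_scan(cbind(a = rep(3, 10)), cbind(b = rnorm(10))),
               "\\[0, 2\\]")
})

test_that("meqtl_scan's nominal flags hold their level under the null", {
  set.seed(23)
  n <- 150
  snps <- matrix(rbinom(n * 10, 2, 0.3), n,
                 dimnames = list(NULL, paste0("s", 1:10)))
  cpgs <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("c", 1:10)))
  res <- meqtl_scan(snps, cpgs)
  expect_equal(nrow(res), 100)
  # binomial(100, 0.05) comfortably below 13
  expect_lte(sum(res$significant), 13)
})

test_that("group_contrast matches the textbook pooled t-test", {
  set.seed(29)
  v <- c(rnorm(12, 0), rnorm(15, 0.8), rnorm(9, 1.6))
  g <- rep(c("ige-/sx-", "ige+/sx-", "ige+/sx+"), c(12, 15, 9))
  res <- group_contrast(v, g)
  expect_equal(nrow(res), 3)
  pick <- res$group1 == "ige-/sx-" & res$group2 == "ige+/sx+"
  o <- oracle_pooled_t(v[g == "ige-/sx-"], v[g == "ige+/sx+"])
  expect_equal(res$t[pick], o$t, tolerance = 1e-10)
  expect_equal(res$p[pick], o$p, tolerance = 1e-10)
  expect_equal(res$df[pick], o$df)
  # tiers are consistent with the p-values
  expect_identical(res$tier[res$p >= 0.05], rep("ns", sum(res$p >= 0.05)))
  expect_true(all(res$tier[res$p < 1e-4] == "****"))
})

test_that("group_contrast handles identical groups and bad input", {
  v <- rep(c(1, 2, 3, 4), 2)
  g <- rep(c("a", "b"), each = 4)
  res <- group_contrast(v, g)
  expect_equal(res$p, 1)  # identical distributions, zero mean difference
  expect_error(group_contrast(v, g, pairs = list(c("a", "zzz"))), "zzz")
  expect_error(group_contrast(c(1, 2, 3), c("a", "a", "b")), "fewer than 2")
  expect_error(group_contrast(1:3, c("a", "b")), "equal length")
})

test_that("group_contrast has power on the simulated severity gradient", {
  cfg <- sim_config(n_samples = 3000, prevalence = 0.4, seed = 33,
                    n_nasal_cpg = 10, n_blood_cpg = 5, n_snp = 5)
  sim <- simulate_cohort(cfg)
  ph <- sim$cohort$phenotype
  m <- sim$cohort$layers$nasal_meth[, sim$truth$causal_cpg_ids[1]]
  grp <- ifelse(ph$allergy == 1, "case", "control")
  res <- group_contrast(m, grp)
  expect_lt(res$p, 1e-10)
  expect_identical(res$tier, "****")
  # cases have the lower methylation mean
  means <- setNames(c(res$mean1, res$mean2), c(res$group1, res$group2))
  expect_lt(means[["case"]], means[["control"]])
})
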
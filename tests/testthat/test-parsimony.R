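test_that("rank_product reproduces hand-computed geometric means", {
  # A is ranked 1,2,3 over the runs -> (1*2*3)^(1/3) = 6^(1/3);
  # B is ranked 2,1,1 -> 2^(1/3), so B wins despite one worse run
  imp <- rbind(c(A = 9, B = 5, C = 1),
               c(A = 5, B = 9, C = 1),
               c(A = 1, B = 9, C = 5))
  rt <- rank_product(imp)
  expect_s3_class(rt, "rank_table")
  expect_equal(rt$rank_product[rt$feature == "A"], 6^(1 / 3))
  expect_equal(rt$rank_product[rt$feature == "B"], 2^(1 / 3))
  expect_equal(rt$feature[1], "B")  # smallest rank product first
  # all-zero tie block: both features get the average rank everywhere
  tied <- rbind(c(x = 0, y = 0), c(x = 0, y = 0))
  expect_equal(rank_product(tied)$rank_product, c(1.5, 1.5))
})

test_that("rank_product matches the literal oracle and ignores run order", {
  set.seed(6)
  imp <- matrix(round(rexp(8 * 7), 1), 8,
                dimnames = list(NULL, paste0("f", 1:7)))
  rt <- rank_product(imp)
  oracle <- oracle_rank_product(imp)
  expect_equal(rt$rank_product[match(names(oracle), rt$feature)],
               unname(oracle))
  shuffled <- rank_product(imp[sample(8), ])
  expect_identical(shuffled, rt)
  expect_error(rank_product(imp * NA), "missing")
  expect_error(rank_product(unname(imp)), "name")
})

test_that("corrected_cv_ttest reproduces a worked example exactly", {
  # k = 2, r = 2, diffs 0.02, 0.04, 0.02, 0.04:
  # mean 0.03, var = 4e-4/3, ratio 1, t = 0.03/sqrt(1.25 * 4e-4/3)
  tst <- corrected_cv_ttest(c(0.02, 0.04, 0.02, 0.04), k = 2, r = 2)
  expect_equal(tst$mean_diff, 0.03)
  expect_equal(tst$t, 0.03 / sqrt((1 / 4 + 1) * var(c(0.02, 0.04, 0.02, 0.04))))
  expect_equal(tst$df, 3)
  expect_equal(tst$p_value, 2 * pt(-abs(tst$t), 3))
})

test_that("the correction deflates the naive paired t by a fixed factor", {
  set.seed(13)
  k <- 5; r <- 4; m <- k * r
  d <- rnorm(m, 0.01, 0.03)
  tst <- corrected_cv_ttest(d, k, r)
  t_naive <- mean(d) / sqrt(var(d) / m)
  ratio <- 1 / (k - 1)
  expect_equal(tst$t, t_naive / sqrt(1 + m * ratio))
  expect_gt(abs(t_naive), abs(tst$t))  # correction is conservative
  # degenerate all-equal differences
  dg <- corrected_cv_ttest(rep(0, 4), 2, 2)
  expect_true(dg$degenerate)
  expect_equal(dg$p_value, 1)
  dg2 <- corrected_cv_ttest(rep(0.1, 4), 2, 2)
  expect_equal(dg2$p_value, 0)
  expect_error(corrected_cv_ttest(1:5, 2, 2), "k\\*r")
})

test_that("incremental selection stops at the first non-significant gain", {
  cfg <- toy_config(71, n = 220, delta = 1.6, rho = 0.2)
  sim <- simulate_cohort(cfg)
  X <- sim$cohort$layers$nasal_meth
  y <- sim$cohort$phenotype$allergy
  ranked <- c(sim$truth$causal_cpg_ids,
              setdiff(colnames(X), sim$truth$causal_cpg_ids)[1:3])
  sel <- incremental_selection(X, y, ranked, max_size = 5,
                               stop_alpha = 0.05,
                               settings = fast_settings(2, k = 5, r = 4))
  expect_s3_class(sel, "incremental_path")
  expect_equal(nrow(sel$path), 5)
  expect_true(is.na(sel$path$p_vs_previous[1]))
  expect_identical(sel$selected_features,
                   sel$path$feature_added[seq_len(sel$selected_size)])
  # selected size is exactly the position before the first p >= alpha
  first_ns <- which(sel$path$p_vs_previous >= 0.05)[1]
  expected <- if (is.na(first_ns)) 5L else first_ns - 1L
  expect_identical(sel$selected_size, expected)
  # noise additions after the causal features must not look significant
  expect_lte(sel$selected_size, 4L)
})

test_that("on a pure-noise cohort the rule selects a single feature", {
  cfg <- toy_config(72, n = 200, delta = 0)
  sim <- simulate_cohort(cfg)
  X <- sim$cohort$layers$nasal_meth[, 1:6]
  y <- sim$cohort$phenotype$allergy
  sel <- incremental_selection(X, y, colnames(X), max_size = 4,
                               settings = fast_settings(4, k = 5, r = 4))
  expect_identical(sel$selected_size, 1L)
})

test_that("raising stop_alpha can only grow the selected panel", {
  cfg <- toy_config(73, n = 200, delta = 1.2)
  sim <- simulate_cohort(cfg)
  X <- sim$cohort$layers$nasal_meth
  y <- sim$cohort$phenotype$allergy
  ranked <- c(sim$truth$causal_cpg_ids, colnames(X)[1:2])
  sizes <- vapply(c(0.01, 0.05, 0.5, 1), function(a) {
    incremental_selection(X, y, unique(ranked), max_size = 4,
                          stop_alpha = a,
                          settings = fast_settings(8, k = 5, r = 2))$selected_size
  }, integer(1))
  # growth continues while p < stop_alpha, so a looser threshold keeps
  # adding features for longer: sizes are non-decreasing in stop_alpha
  expect_true(all(diff(sizes) >= 0))
  expect_identical(sizes[4], 4L)  # p < 1 strictly, so alpha = 1 never stops
})

test_that("compare_panels pairs folds and detects a planted advantage", {
  cfg <- toy_config(74, n = 240, delta = 1.8, rho = 0)
  sim <- simulate_cohort(cfg)
  X <- sim$cohort$layers$nasal_meth
  y <- sim$cohort$phenotype$allergy
  causal <- sim$truth$causal_cpg_ids
  noise <- setdiff(colnames(X), causal)[1:3]
  st <- fast_settings(9, k = 5, r = 4)
  cmp <- compare_panels(X, y, causal, noise, settings = st)
  expect_lt(cmp$test$p_value, 0.05)
  expect_gt(cmp$test$mean_diff, 0)
  # a panel compared against itself is exactly degenerate
  self <- compare_panels(X, y, causal, causal, settings = st)
  expect_true(self$test$degenerate)
  expect_equal(self$test$p_value, 1)
  expect_error(compare_panels(X, y, causal, "nope", settings = st), "nope")
})
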
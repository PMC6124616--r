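test_that("Wald arithmetic is correct at reference points", {
  expect_equal(wald_test(fake_fit(m = 0), "maternal")$p_value, 1)
  p196 <- wald_test(fake_fit(f = 1.96, se_f = 1), "fetal")$p_value
  expect_equal(p196, 0.05, tolerance = 1e-3)
  # monotone decreasing p in the statistic
  ps <- vapply(c(0.5, 1, 2, 3),
               function(z) wald_test(fake_fit(f = z, se_f = 1), "fetal")$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(wald_test(fake_fit(), "nope"))
})

test_that("the optimizer reproduces the closed-form moment solution on complete data", {
  # with complete data the full model is just-identified, so the MLE solves
  # the moment equations exactly: an independent algebraic route
  cfg <- scenario_config(n_families = 30000, v_fetal = 4e-4,
                         v_maternal = -2e-4, seed = 21)
  d <- simulate_dyads(cfg)
  fit <- fit_sem(d)
  expect_true(fit$converged)
  s <- group_summaries(d)$both
  phi_hat <- s$cov["snp", "snp"]
  c1 <- s$cov["bw", "snp"] / phi_hat
  c2 <- s$cov["bw_offspring", "snp"] / phi_hat
  expect_equal(unname(fit$theta["f"]), (4 * c1 - 2 * c2) / 3, tolerance = 1e-5)
  expect_equal(unname(fit$theta["m"]), (4 * c2 - 2 * c1) / 3, tolerance = 1e-5)
  expect_equal(exp(unname(fit$theta["log_phi"])), unname(phi_hat),
               tolerance = 1e-5)
  # and the generating values are recovered within 3 reported SEs
  tr <- scenario_truth(cfg)
  expect_lt(abs(fit$theta["f"] - tr$f), 3 * fit$se["f"])
  expect_lt(abs(fit$theta["m"] - tr$m), 3 * fit$se["m"])
})

test_that("raw-data and covariance-summary fits agree", {
  cfg <- scenario_config(n_families = 8000, v_fetal = 9e-4, seed = 31)
  d <- simulate_dyads(cfg)
  f_cov <- fit_sem(d, engine = "cov")
  f_raw <- fit_sem(d, engine = "raw")
  expect_lt(max(abs(f_cov$theta - f_raw$theta)), 1e-4)
  expect_equal(f_cov$neg2ll, f_raw$neg2ll, tolerance = 1e-6)
})

test_that("the full model never fits worse than nested reductions", {
  cfg <- scenario_config(n_families = 5000, v_fetal = 4e-4,
                         v_maternal = 2e-4, seed = 41)
  g <- group_summaries(simulate_dyads(cfg))
  full <- fit_sem(g)
  for (spec in list(model_spec(TRUE, FALSE), model_spec(FALSE, TRUE),
                    model_spec(FALSE, FALSE))) {
    red <- fit_sem(g, spec)
    expect_true(red$converged)
    expect_lte(full$neg2ll, red$neg2ll + 1e-6)
    t <- lrt(full, red)
    expect_gte(t$statistic, 0)
    expect_equal(t$df, 2L - spec$free_maternal - spec$free_fetal)
  }
  # identical specs carry no evidence; frees-a-path reversal is an error
  expect_equal(lrt(full, full)$p_value, 1)
  expect_equal(lrt(full, full)$statistic, 0)
  expect_error(lrt(fit_sem(g, model_spec(TRUE, FALSE)), full), "nested")
})

test_that("linear comparators estimate f + m/2 and m + f/2", {
  cfg <- scenario_config(n_families = 1e6, v_fetal = -4e-4,
                         v_maternal = -1.96e-4, seed = 51)
  d <- simulate_dyads(cfg)
  tr <- scenario_truth(cfg)   # f = -0.020, m = -0.014
  lmres <- linear_model_effects(d)
  b_f <- lmres$beta[lmres$effect == "fetal"]
  b_m <- lmres$beta[lmres$effect == "maternal"]
  se_f <- lmres$se[lmres$effect == "fetal"]
  se_m <- lmres$se[lmres$effect == "maternal"]
  expect_lt(abs(b_f - (tr$f + tr$m / 2)), 3 * se_f)   # -0.027 at these values
  expect_lt(abs(b_m - (tr$m + tr$f / 2)), 3 * se_m)
  expect_equal(tr$f + tr$m / 2, -0.027)
  # degenerate inputs
  expect_error(linear_model_effects(
    data.frame(bw = rnorm(10), bw_offspring = rnorm(10), dosage = 1)),
    "constant genotype")
})

test_that("heterogeneity statistics match hand computation and metafor", {
  h <- heterogeneity_i2(0.05, 0.02, -0.01, 0.02)
  expect_equal(h$Q, 4.5)
  expect_equal(h$I2, (4.5 - 1) / 4.5 * 100, tolerance = 1e-10)
  expect_equal(h$p, pchisq(4.5, 1, lower.tail = FALSE))
  expect_lt(abs(h$p - 0.034), 0.001)
  # independent route: fixed-effect meta-analysis machinery
  skip_if_not_installed("metafor")
  rma <- metafor::rma(yi = c(0.05, -0.01), sei = c(0.02, 0.02), method = "FE")
  expect_equal(h$Q, unname(rma$QE), tolerance = 1e-8)
  expect_equal(h$p, unname(rma$QEp), tolerance = 1e-8)
  # identical estimates: no heterogeneity
  h0 <- heterogeneity_i2(0.03, 0.01, 0.03, 0.02)
  expect_equal(h0$Q, 0)
  expect_equal(h0$I2, 0)
  expect_equal(h0$p, 1)
  # doubling both SEs quarters Q
  h2 <- heterogeneity_i2(0.05, 0.04, -0.01, 0.04)
  expect_equal(h2$Q, h$Q / 4)
})

test_that("summary statistics reconstruct a cohort's sufficient statistics", {
  expect_equal(summary_stats_to_group(0.5, 0.02, 1, 100, "fetal_arm")$cov[1, 2],
               0.01)
  expect_equal(summary_stats_to_group(0.5, 0.02, 1, 100, "fetal_arm")$cov[2, 2],
               0.5)
  expect_error(summary_stats_to_group(0.5, 3, 1, 100, "fetal_arm"),
               "correlation")
  expect_error(summary_stats_to_group(1.2, 0.1, 1, 100, "fetal_arm"), "eaf")
  # round trip: summaries of a simulated own-phenotype cohort (raw dosages)
  cfg <- scenario_config(n_families = 2e5, v_fetal = 9e-4, p = 0.3, seed = 61)
  d <- simulate_dyads(cfg)
  raw_dosage <- d$dosage * sqrt(2 * cfg$p * (1 - cfg$p)) + 2 * cfg$p
  eaf_hat <- mean(raw_dosage) / 2
  beta_hat <- coef(lm(d$bw ~ raw_dosage))[["raw_dosage"]]
  n <- nrow(d)
  rebuilt <- summary_stats_to_group(eaf_hat, beta_hat,
                                    var(d$bw) * (n - 1) / n, n, "fetal_arm")
  direct <- group_summary("own_only", n, c(mean(d$bw), mean(raw_dosage)),
                          cov(cbind(d$bw, raw_dosage)) * (n - 1) / n)
  expect_equal(rebuilt$cov, direct$cov, tolerance = 5e-3)
  expect_equal(rebuilt$mean[["snp"]], direct$mean[["snp"]], tolerance = 5e-3)
  expect_identical(rebuilt$pattern, "own_only")
  expect_identical(summary_stats_to_group(0.2, 0, 1, 10, "maternal_arm")$pattern,
                   "offspring_only")
})

test_that("adding a summary-statistic maternal arm sharpens the maternal path", {
  # all groups must share the dosage scale; use raw 0-2 allele counts
  to_raw <- function(d, p) {
    d$dosage <- d$dosage * sqrt(2 * p * (1 - p)) + 2 * p
    d
  }
  cfg <- scenario_config(n_families = 30000, v_maternal = 2e-4, seed = 71)
  d1 <- to_raw(simulate_dyads(cfg), cfg$p)
  g_both <- group_summaries(d1)
  fit_alone <- fit_sem(g_both)
  # an external offspring-phenotype-only cohort shared only as summaries
  cfg2 <- scenario_config(n_families = 30000, v_maternal = 2e-4, seed = 72)
  d2 <- to_raw(simulate_dyads(cfg2), cfg2$p)
  n2 <- nrow(d2)
  arm <- summary_stats_to_group(
    eaf = mean(d2$dosage) / 2,
    beta = coef(lm(d2$bw_offspring ~ d2$dosage))[[2]],
    pheno_var = var(d2$bw_offspring) * (n2 - 1) / n2, n = n2,
    which = "maternal_arm")
  fit_joint <- fit_sem(c(g_both, list(arm)))
  expect_true(fit_joint$converged)
  expect_lt(fit_joint$se[["m"]], fit_alone$se[["m"]])
  # the maternal estimate itself stays near truth
  expect_lt(abs(fit_joint$theta[["m"]] - scenario_truth(cfg)$m / sqrt(0.5)),
            3 * fit_joint$se[["m"]])
})
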
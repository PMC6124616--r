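test_that("implied moments reduce to the identity under the global null", {
  p <- path_model_params(m = 0, f = 0, phi = 1, var_e = 1, var_eo = 1, rho = 0)
  mom <- implied_moments(p, "both")
  expect_equal(unname(mom$cov), diag(3))
  expect_equal(unname(mom$mean), c(0, 0, 0))
  # genotype-phenotype covariances are exactly zero when both paths vanish
  p2 <- path_model_params(m = 0, f = 0, phi = 2.3, var_e = 0.7, var_eo = 0.9,
                          rho = 0.2)
  expect_identical(implied_moments(p2)$cov["bw", "snp"], 0)
  expect_identical(implied_moments(p2)$cov["bw_offspring", "snp"], 0)
})

test_that("path-traced covariances match hand-derived values and submatrices", {
  # f-only variant: Cov(BW,SNP) = phi*f, Cov(BW_O,SNP) = phi*f/2
  m1 <- implied_moments(path_model_params(m = 0, f = 0.02))
  expect_equal(m1$cov["bw", "snp"], 0.020)
  expect_equal(m1$cov["bw_offspring", "snp"], 0.010)
  # mixed-sign variant: phi*(f + m/2) and phi*(m + f/2)
  m2 <- implied_moments(path_model_params(m = -0.014, f = 0.020))
  expect_equal(m2$cov["bw", "snp"], 0.013)
  expect_equal(m2$cov["bw_offspring", "snp"], -0.004)
  # reduced patterns are submatrices of the full pattern
  full <- implied_moments(path_model_params(m = 0.1, f = -0.2, rho = 0.25))
  for (pat in c("own_only", "offspring_only")) {
    sub <- implied_moments(path_model_params(m = 0.1, f = -0.2, rho = 0.25), pat)
    vars <- pattern_vars(pat)
    expect_equal(sub$cov, full$cov[vars, vars])
    expect_equal(sub$mean, full$mean[vars])
  }
})

test_that("implied covariances match empirical moments of simulated dyads", {
  # Monte-Carlo oracle at n = 1e6 across the scenario effect grid
  n <- 1e6
  grid <- expand.grid(v_f = c(0, 4e-4), v_m = c(0, -2e-4))
  for (i in seq_len(nrow(grid))) {
    cfg <- scenario_config(n_families = n, v_fetal = grid$v_f[i],
                           v_maternal = grid$v_m[i], seed = 100 + i)
    d <- simulate_dyads(cfg)
    tr <- scenario_truth(cfg)
    p <- path_model_params(m = tr$m, f = tr$f, phi = 1,
                           var_e = tr$var_e + cfg$beta_u^2,
                           var_eo = tr$var_eo + cfg$beta_u^2, rho = tr$rho)
    emp <- cov(cbind(d$bw, d$bw_offspring, d$dosage)) * (n - 1) / n
    # entrywise MC standard error is at most ~ sqrt(2)/sqrt(n) here
    expect_lt(max(abs(emp - unname(implied_moments(p)$cov))), 3 * 1.5 / sqrt(n))
  }
})

test_that("parameter invariants are enforced and non-PD points are signalled", {
  expect_error(path_model_params(phi = -1), class = "dyadsem_invalid_params")
  expect_error(path_model_params(var_e = 0), class = "dyadsem_invalid_params")
  expect_error(path_model_params(rho = 1.5, var_e = 1, var_eo = 1),
               class = "dyadsem_invalid_params")
  # at the residual-correlation boundary the implied matrix is singular
  p_edge <- path_model_params(m = 0, f = 0, var_e = 1, var_eo = 1, rho = 1)
  expect_error(implied_moments(p_edge), class = "dyadsem_invalid_params")
  g <- group_summary("both", 10, c(0, 0, 0), diag(3))
  expect_error(neg2_loglik_cov(p_edge, list(g)),
               class = "dyadsem_invalid_params")
  expect_identical(neg2_loglik_cov(p_edge, list(g), on_invalid = "inf"), Inf)
})

test_that("a record at the implied mean contributes log|Sigma| + k log(2pi)", {
  p <- path_model_params(m = 0.05, f = -0.02, phi = 1.2, var_e = 0.8,
                         var_eo = 0.9, rho = 0.2, mu_bw = 0.3, mu_snp = 1)
  mom <- implied_moments(p, "both")
  d <- data.frame(family_id = 1, bw = mom$mean["bw"],
                  bw_offspring = mom$mean["bw_offspring"],
                  dosage = mom$mean["snp"])
  expect_equal(neg2_loglik_raw(p, d),
               determinant(mom$cov, logarithm = TRUE)$modulus[[1]] +
                 3 * log(2 * pi))
})

test_that("the likelihood is additive over patterns and order-invariant", {
  cfg <- small_config(n_families = 3000, missing_design = "iii")
  d <- simulate_dyads(cfg)
  p <- path_model_params(m = 0.01, f = 0.02, var_e = 0.9, var_eo = 0.9,
                         rho = 0.25)
  whole <- neg2_loglik_raw(p, d)
  parts <- sum(vapply(split(d, d$pattern), function(s) neg2_loglik_raw(p, s),
                      numeric(1)))
  expect_equal(whole, parts)
  # shuffling records (and the group list) changes nothing
  shuffled <- d[sample.int(nrow(d)), ]
  expect_equal(neg2_loglik_raw(p, shuffled), whole)
  g <- group_summaries(d)
  expect_equal(neg2_loglik_cov(p, g), neg2_loglik_cov(p, rev(g)))
})

test_that("raw-record FIML equals the covariance-summary objective", {
  for (design in c("complete", "iii")) {
    cfg <- small_config(n_families = 4000, missing_design = design, seed = 9)
    d <- simulate_dyads(cfg)
    p <- path_model_params(m = -0.01, f = 0.03, var_e = 0.85, var_eo = 0.95,
                           rho = 0.2)
    expect_equal(neg2_loglik_raw(p, d), neg2_loglik_cov(p, group_summaries(d)),
                 tolerance = 1e-10)
  }
})

test_that("group summaries validate their inputs", {
  expect_error(group_summary("both", 3, c(0, 0, 0), diag(3)),
               "sample size")
  asym <- diag(3); asym[1, 2] <- 0.5
  expect_error(group_summary("both", 10, c(0, 0, 0), asym), "symmetric")
  expect_error(group_summaries(data.frame(bw = 1, bw_offspring = 2)),
               "requires columns")
})
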
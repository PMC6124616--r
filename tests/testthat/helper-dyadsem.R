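# shared fixtures for the test suite; everything is generated in code

# small complete-data scenario, cheap enough for structural tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_families = 2000, v_fetal = 0.01, v_maternal = 0.005,
         n_replicates = 5, seed = 42L),
    list(...))
  do.call(scenario_config, args)
}

# a hand-built sem_fit-shaped object for testing the Wald arithmetic alone
fake_fit <- function(m = 0, f = 0, se_m = 1, se_f = 1) {
  structure(list(spec = model_spec(TRUE, TRUE),
                 theta = c(m = m, f = f),
                 se = c(m = se_m, f = se_f),
                 n_by_pattern = c(both = 100)),
            class = "sem_fit")
}

# Monte-Carlo standard error of a proportion
prop_se <- function(p, n) sqrt(p * (1 - p) / n)

expect_rate_near <- function(observed, expected, n_rep, label = NULL) {
  tol <- 3 * prop_se(max(min(expected, 0.99), 0.01), n_rep)
  expect_lt(abs(observed - expected), max(tol, 0.005), label = label)
}
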
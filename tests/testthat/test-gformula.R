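fitted_models <- function(arm, n = 600, seed = 11) {
  memo(sprintf("gf_models_%d_%d_%d", arm, n, seed), {
    trial <- feedback_trial(n, seed)
    fit_gformula_models(trial$table, default_gformula_spec(), arm = arm)
  })
}

test_that("component models respect their eligibility restrictions", {
  trial <- feedback_trial(600, seed = 11)
  m <- fitted_models(0)
  tab <- trial$table[trial$table$arm == 0, ]
  # the death model never sees pre-progression person-time
  expect_equal(m$outcome$n, sum(tab$dp == 1))
  # absorbing progression model fitted only where previously 0
  lag <- ppswitch:::add_lagged_covariates(tab)
  expect_equal(m$models$dp$fit$n, sum(lag$lag_dp == 0))
  # transition models exclude month-0 rows
  expect_equal(m$models$tls$fit$n, sum(lag$k >= 1))
  expect_false(m$failed)
})

test_that("gaussian residual SD equals the root-mean-square residual", {
  m <- fitted_models(0)
  trial <- feedback_trial(600, seed = 11)
  tab <- ppswitch:::add_lagged_covariates(
    trial$table[trial$table$arm == 0, ])
  sub <- tab[tab$k >= 1, ]
  mu <- ppswitch:::predict_gaussian(m$models$tls$fit, sub)
  expect_equal(m$models$tls$fit$sigma,
               sqrt(mean((sub$tls - mu)^2)), tolerance = 1e-10)
})

test_that("the treatment variable is dropped where it is constant", {
  m1 <- fitted_models(1)
  expect_match(m1$models$dp$note, "lag_treatment")
  expect_false("treatment" %in% names(m1$outcome$coef))
})

test_that("an absorbing covariate at 1 for everyone simulates as 1", {
  cfg <- feedback_config()
  cfg$progression["intercept"] <- 20
  cfg$progression["treatment"] <- 0
  cfg$progression["tls10"] <- 0; cfg$progression["ecog"] <- 0
  cfg$n_control <- 150; cfg$n_experimental <- 0; cfg$seed <- 9
  suppressWarnings(trial <- generate_trial(cfg))
  m <- fit_gformula_models(trial$table, default_gformula_spec(), arm = 0)
  expect_true(m$models$dp$skipped)
  res <- simulate_counterfactual(m, "always_control", n_sim = 500, seed = 2)
  expect_equal(res$covariate_means$dp, rep(1, 48))
})

test_that("simulation audit confirms intervention and restrictions", {
  m <- fitted_models(0)
  res <- simulate_counterfactual(m, "always_control", n_sim = 2000, seed = 3)
  expect_true(res$audit$treatment_constant)
  expect_true(res$audit$risk_monotone)
  expect_true(res$audit$absorbing_respected)
  expect_true(res$audit$death_gated_by_progression)
  expect_true(all(diff(res$risk$risk) >= 0))
  expect_true(all(res$risk$risk >= 0 & res$risk$risk <= 1))
})

test_that("strategies coincide when treatment is in no fitted pathway", {
  trial <- null_trial(500, seed = 19)
  m <- fit_gformula_models(trial$table, default_gformula_spec(), arm = 0)
  r0 <- simulate_counterfactual(m, "always_control", n_sim = 4000, seed = 7)
  r1 <- simulate_counterfactual(m, "always_experimental", n_sim = 4000,
                                seed = 7)
  se <- sqrt(r0$risk$mc_se^2 + r1$risk$mc_se^2)
  # treatment coefficients are estimated near zero on null data, so the two
  # forced strategies differ only through those small estimates
  expect_lt(abs(r0$risk$risk[48] - r1$risk$risk[48]),
            4 * max(se[48], 0.02))
})

test_that("natural course tracks the observed experimental arm", {
  trial <- feedback_trial(600, seed = 11)
  m <- fitted_models(1)
  nc <- natural_course_check(m, trial$table, n_sim = 8000, seed = 5,
                             tolerance = 0.05)
  risk_rows <- nc[nc$quantity == "risk" & nc$month %in% c(12, 24, 36, 48), ]
  obs_n <- sum(trial$table$arm == 1 & trial$table$k == 0)
  band <- 3 * (risk_rows$mc_se +
                 sqrt(pmax(risk_rows$observed * (1 - risk_rows$observed),
                           0.01) / obs_n))
  expect_true(all(risk_rows$abs_diff <= band))

  # zero tolerance fails on any stochastic run; the observed column equals
  # direct per-month averages
  nc0 <- natural_course_check(m, trial$table, n_sim = 2000, seed = 5,
                              tolerance = 0)
  expect_false(all(nc0$pass))
  tab1 <- trial$table[trial$table$arm == 1, ]
  dp12 <- mean(tab1$dp[tab1$k == 11])
  expect_equal(nc$observed[nc$quantity == "dp" & nc$month == 12], dp12)
})

test_that("effect measures derive from the stored risk curves", {
  m0 <- fitted_models(0); m1 <- fitted_models(1)
  r0 <- simulate_counterfactual(m0, "always_control", n_sim = 3000, seed = 8)
  r1 <- simulate_counterfactual(m1, "always_experimental", n_sim = 3000,
                                seed = 9)
  eff <- gformula_effects(r0, r1, horizon = 48)
  expect_equal(eff$rr, r1$risk$risk[48] / r0$risk$risk[48],
               tolerance = 1e-12)
  expect_equal(eff$chr,
               log(1 - r1$risk$risk[48]) / log(1 - r0$risk$risk[48]),
               tolerance = 1e-12)
  same <- gformula_effects(r0, r0, horizon = 48)
  expect_equal(same$rr, 1); expect_equal(same$chr, 1)
  r_short <- r0; r_short$risk <- r_short$risk[1:24, ]
  expect_error(gformula_effects(r_short, r1), "mismatched horizons")
})
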
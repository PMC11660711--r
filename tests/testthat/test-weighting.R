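# craft a pooled_logistic object with known coefficients so that weight
# arithmetic can be checked against hand-computed products
stub_logistic <- function(coef_named, terms, data) {
  structure(list(coef = coef_named, vcov = diag(length(coef_named)),
                 converged = TRUE, separated = FALSE, n = nrow(data),
                 design = design_build(data, terms), outcome = "event",
                 weighted = FALSE),
            class = "pooled_logistic")
}

test_that("stabilized and unstabilized weights match hand-computed products", {
  # one control subject, progression at 1, eligible intervals k = 1, 2;
  # denominator switch probabilities (0.2, 0.25), numerator (0.1, 0.1)
  pt <- data.frame(
    subject_id = "S1", k = 0:2, arm = 0,
    treatment = 0, dp = c(0, 1, 1), icp = 0, ecog_tv = 0,
    tls = 50, tdp = c(0, 0, 1), outcome = 0, censored = 0, switched = 0,
    age = 60, ecog = 0, ics = 0, race = 0, sex = 0, smoking = 1,
    strata = 1, ids = 4, li = 1, rt = 0, tls0 = 50,
    stringsAsFactors = FALSE)
  # logit p = a + b * k hitting 0.2 at k = 1 and 0.25 at k = 2
  b <- qlogis(0.25) - qlogis(0.2)
  a <- qlogis(0.2) - b
  den <- stub_logistic(c("(Intercept)" = a, k = b), term_list(k = "linear"),
                       pt)
  num <- stub_logistic(c("(Intercept)" = qlogis(0.1)), list(), pt)
  fits <- structure(list(
    spec = weight_spec("switching", denominator = term_list(k = "linear")),
    fits = list(control = list(num = num, den = den, failed = FALSE))),
    class = "weight_fits")
  ws <- compute_weights(fits, pt)
  expect_equal(ws$k, 0:2)
  expect_equal(ws$stabilized[1], 1)        # pre-progression: weight 1
  expect_equal(ws$stabilized[2], 0.9 / 0.8, tolerance = 1e-12)
  expect_equal(ws$stabilized[3], (0.9 / 0.8) * (0.9 / 0.75),
               tolerance = 1e-12)
  expect_equal(ws$unstabilized[3], 1 / (0.8 * 0.75), tolerance = 1e-12)
})

test_that("deterministic weight-of-1 rules hold on generated data", {
  trial <- feedback_trial(300, seed = 21)
  ws <- compute_weights(fit_weight_models(trial$table, full_switch_spec()),
                        trial$table)
  tab <- trial$table
  key <- paste(tab$subject_id, tab$k)
  idx <- match(paste(ws$subject_id, ws$k), key)
  # experimental arm: switching weight 1 at every interval
  expect_true(all(ws$stabilized[tab$arm[idx] == 1] == 1))
  # control subjects at or before progression: weight 1
  pre <- tab$arm[idx] == 0 & tab$dp[idx] == 0
  expect_true(all(ws$stabilized[pre] == 1))
  # weights strictly positive everywhere
  expect_true(all(ws$stabilized > 0 & ws$unstabilized > 0))
})

test_that("numerator identical to denominator gives stabilized weights of 1", {
  trial <- feedback_trial(300, seed = 21)
  spec <- weight_spec("switching",
                      denominator = list(term_spec("k", "linear")),
                      numerator = list(term_spec("k", "linear")))
  ws <- compute_weights(fit_weight_models(trial$table, spec), trial$table)
  expect_true(all(abs(ws$stabilized - 1) < 1e-10))
})

test_that("switching weights require post-progression person-time", {
  trial <- feedback_trial(300, seed = 21)
  none <- trial$table[trial$table$dp == 0, ]
  expect_error(fit_weight_models(none, full_switch_spec()),
               "post-progression")
})

test_that("combining weight series multiplies elementwise with loop oracle", {
  trial <- feedback_trial(300, seed = 21)
  a <- compute_weights(fit_weight_models(trial$table, full_switch_spec()),
                       trial$table)
  b <- compute_weights(fit_weight_models(trial$table, ltfu_time_spec()),
                       trial$table)
  ab <- combine_weights(a, b)

  ones <- b
  ones$stabilized <- 1; ones$unstabilized <- 1
  a_again <- combine_weights(a, ones)
  expect_equal(a_again$stabilized,
               a$stabilized[match(paste(a_again$subject_id, a_again$k),
                                  paste(a$subject_id, a$k))])

  aa <- combine_weights(a, a)
  expect_equal(aa$stabilized, a$stabilized[
    match(paste(aa$subject_id, aa$k), paste(a$subject_id, a$k))]^2,
    tolerance = 1e-12)

  # diagnostics equal directly looped moments of the products
  key_b <- paste(b$subject_id, b$k)
  prod_loop <- numeric(0)
  for (i in seq_len(nrow(a))) {
    j <- match(paste(a$subject_id[i], a$k[i]), key_b)
    if (!is.na(j)) {
      prod_loop <- c(prod_loop, a$stabilized[i] * b$stabilized[j])
    }
  }
  dg <- attr(ab, "diagnostics")
  expect_equal(dg$mean, mean(prod_loop), tolerance = 1e-12)
  expect_equal(dg$sd, sd(prod_loop), tolerance = 1e-12)
})

test_that("percentile truncation clips to sort-based empirical quantiles", {
  trial <- feedback_trial(300, seed = 21)
  ws <- compute_weights(fit_weight_models(trial$table, full_switch_spec()),
                        trial$table)
  expect_equal(truncate_weights(ws, 0, 100)$stabilized, ws$stabilized)

  t5 <- truncate_weights(ws, 5, 95)
  w <- sort(ws$stabilized)
  n <- length(w)
  # type-7 empirical quantile computed from first principles
  q_manual <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h)
    w[lo] + (h - lo) * (w[min(lo + 1, n)] - w[lo])
  }
  expect_equal(t5$stabilized,
               pmin(pmax(ws$stabilized, q_manual(0.05)), q_manual(0.95)),
               tolerance = 1e-12)

  t50 <- truncate_weights(ws, 50, 50)
  expect_equal(unique(t50$stabilized), q_manual(0.5), tolerance = 1e-12)

  # narrowing the window never increases the weight SD
  sds <- sapply(list(c(0, 100), c(1, 99), c(5, 95), c(25, 75), c(50, 50)),
                function(tr) sd(truncate_weights(ws, tr[1], tr[2])$stabilized))
  expect_true(all(diff(sds) <= 1e-12))
})

test_that("weight diagnostics summarize person-time moments and flag extremes", {
  ws1 <- ppswitch:::new_weight_series(
    data.frame(subject_id = "a", k = 0:2, stabilized = c(1, 1, 1),
               unstabilized = c(1, 1, 1)))
  d1 <- weight_diagnostics(ws1)
  expect_equal(d1$mean, 1); expect_equal(d1$sd, 0)
  expect_false(d1$flag_mean); expect_false(d1$flag_max)

  ws2 <- ppswitch:::new_weight_series(
    data.frame(subject_id = "a", k = 0:2, stabilized = c(0.5, 1, 1.5),
               unstabilized = c(0.5, 1, 1.5)))
  d2 <- weight_diagnostics(ws2)
  expect_equal(d2$mean, 1); expect_equal(d2$min, 0.5); expect_equal(d2$max, 1.5)

  ws3 <- ppswitch:::new_weight_series(
    data.frame(subject_id = "a", k = 0:20,
               stabilized = c(rep(1, 20), 30),
               unstabilized = c(rep(1, 20), 30)))
  expect_true(weight_diagnostics(ws3)$flag_max)
})

test_that("weights are non-anticipating", {
  trial <- feedback_trial(300, seed = 21)
  tab <- trial$table
  full <- compute_weights(fit_weight_models(tab, full_switch_spec()), tab)
  kcut <- 12
  # refit and recompute on the truncated data: weights at k <= kcut with the
  # same fitted models must not depend on later rows
  fits <- fit_weight_models(tab, full_switch_spec())
  cut <- compute_weights(fits, tab[tab$k <= kcut, ])
  key_full <- paste(full$subject_id, full$k)
  idx <- match(paste(cut$subject_id, cut$k), key_full)
  expect_equal(cut$stabilized, full$stabilized[idx], tolerance = 1e-12)
})

test_that("covariate screening applies the p-value / odds-ratio rule", {
  set.seed(33)
  n <- 4000
  d <- data.frame(
    noise = rnorm(n), strong = rnorm(n), const = 1,
    k = rep(0:7, length.out = n))
  d$event <- rbinom(n, 1, plogis(-2 + 0.8 * d$strong))
  out <- screen_covariates(d, term_list(noise = "linear", strong = "linear",
                                        const = "linear"), "event")
  expect_equal(out$variable, c("noise", "strong", "const"))
  expect_true(out$selected[out$variable == "strong"])
  expect_match(out$note[out$variable == "const"], "constant")
  # a null covariate with OR ~ 1 and large p is excluded
  expect_false(out$selected[out$variable == "noise"] &&
                 out$p_value[out$variable == "noise"] > 0.2 &&
                 out$or_min[out$variable == "noise"] > 0.75)

  # Monte-Carlo power: a strong true effect is retained in >= 95/100 repeats
  hits <- 0
  for (r in 1:100) {
    set.seed(1000 + r)
    dd <- data.frame(x = rnorm(500))
    dd$event <- rbinom(500, 1, plogis(-1.5 + 0.7 * dd$x))
    sc <- screen_covariates(dd, term_list(x = "linear"), "event")
    hits <- hits + sc$selected[1]
  }
  expect_gte(hits, 95)
})

test_that("stabilized weights average near one on well-specified data", {
  trial <- feedback_trial(600, seed = 11)
  tab <- with_age_plateau(trial$table)
  dg <- weight_diagnostics(
    compute_weights(fit_weight_models(tab, correct_switch_spec()), tab))
  expect_gte(dg$mean, 0.9); expect_lte(dg$mean, 1.1)
})

test_that("stabilized equals unstabilized KM when eligibility opens at baseline", {
  # progression certain at month 0: every control shares the eligibility
  # clock, the time-only numerator cancels within months, and the two KM
  # estimators coincide exactly
  cfg <- feedback_config()
  cfg$progression["intercept"] <- 20
  cfg$progression["treatment"] <- 0
  cfg$progression["tls10"] <- 0; cfg$progression["ecog"] <- 0
  cfg$censoring["intercept"] <- -30
  cfg$n_control <- 400; cfg$n_experimental <- 0; cfg$seed <- 5
  suppressWarnings(trial <- generate_trial(cfg))
  tab <- trial$table
  ws <- compute_weights(fit_weight_models(tab, full_switch_spec()), tab)
  sw_k <- ave(ifelse(tab$switched == 1, tab$k, Inf), tab$subject_id,
              FUN = min)
  d <- tab[tab$k < sw_k, ]
  idx <- match(paste(d$subject_id, d$k), paste(ws$subject_id, ws$k))
  ks <- km_curve(d, ws$stabilized[idx])
  ku <- km_curve(d, ws$unstabilized[idx])
  expect_equal(ks$risk, ku$risk, tolerance = 1e-9)
})

test_that("random switching leaves weighted and unweighted curves aligned", {
  # switching independent of all covariates and a memoryless death hazard:
  # with progression certain at month 0 (so post-progression eligibility is
  # universal), censoring at switch is truly non-informative and the
  # IPC-weighted and unweighted censor-at-switch curves estimate the same
  # quantity — which is also the oracle no-switching risk
  cfg <- feedback_config()
  cfg$progression["intercept"] <- 20
  cfg$progression["treatment"] <- 0
  cfg$progression["tls10"] <- 0; cfg$progression["ecog"] <- 0
  cfg$switching <- c(intercept = qlogis(0.08), tdp = 0, tls10 = 0,
                     ecog = 0, ecog_tdp = 0, age10 = 0)
  cfg$death <- c(intercept = qlogis(0.03), treatment = 0, tls10 = 0,
                 ecog = 0, tdp = 0, icp = 0, age10 = 0)
  cfg$n_control <- 5000; cfg$n_experimental <- 0; cfg$seed <- 14
  suppressWarnings(trial <- generate_trial(cfg))
  tab <- trial$table
  ws <- compute_weights(fit_weight_models(tab, full_switch_spec()), tab)
  sw_k <- ave(ifelse(tab$switched == 1, tab$k, Inf), tab$subject_id,
              FUN = min)
  d <- tab[tab$k < sw_k, ]
  idx <- match(paste(d$subject_id, d$k), paste(ws$subject_id, ws$k))
  w <- ws$unstabilized[idx]
  unw <- km_curve(d)
  wtd <- km_curve(d, w)
  # weight-aware Monte-Carlo band: effective at-risk size per month
  n_eff <- vapply(unw$month, function(m) {
    wm <- w[d$k == m - 1]
    sum(wm)^2 / sum(wm^2)
  }, 0)
  se <- sqrt(pmax(unw$risk * (1 - unw$risk), 0.01) / pmax(n_eff, 1))
  expect_true(all(abs(wtd$risk - unw$risk) <= 3 * pmax(se, 5e-3)))

  # and both recover the geometric no-switching risk
  expected <- 1 - (1 - 0.03)^unw$month
  expect_true(all(abs(unw$risk - expected) <= 3 * pmax(se, 5e-3)))
  expect_true(all(abs(wtd$risk - expected) <= 3 * pmax(se, 5e-3)))
})
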
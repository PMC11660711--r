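# minimal person-time for life-table checks, one subject per death month
make_pt <- function(death_month, censor_month = rep(NA, length(death_month)),
                    arm = rep(0, length(death_month)), horizon = 6) {
  subj <- data.frame(
    subject_id = sprintf("P%02d", seq_along(death_month)),
    arm = arm,
    progression_month = 0,   # death gating satisfied from the start
    switch_month = NA_real_,
    censor_month = censor_month,
    death_month = death_month,
    max_followup_months = horizon,
    stringsAsFactors = FALSE)
  expand_to_person_time(subj, horizon)
}

test_that("life-table hazards and survival match hand counts", {
  # 5 subjects, no deaths over 3 months
  pt <- make_pt(rep(NA_real_, 5), horizon = 3)
  cv <- km_curve(pt)
  expect_equal(cv$survival, c(1, 1, 1))

  # 10 at risk, 2 deaths in month 1; 8 at risk, 1 death in month 2
  dm <- c(0, 0, 1, rep(NA, 7))
  pt <- make_pt(dm, horizon = 2)
  cv <- km_curve(pt)
  expect_equal(cv$hazard, c(2 / 10, 1 / 8))
  expect_equal(cv$survival[2], 0.7)
  expect_equal(cv$n_risk, c(10, 8))
})

test_that("integer-weighted KM equals the row-replication KM", {
  trial <- feedback_trial(150, seed = 4)
  tab <- trial$table[trial$table$arm == 0, ]
  ids <- unique(tab$subject_id)
  set.seed(9)
  w_subj <- sample(1:3, length(ids), replace = TRUE)
  wvec <- w_subj[match(tab$subject_id, ids)]

  weighted <- km_curve(tab, wvec)

  reps <- rep(seq_len(nrow(tab)), times = wvec)
  expect_equal(km_curve(tab[reps, ]), weighted, ignore_attr = TRUE)
})

test_that("unweighted and weighted curves agree with survival::survfit", {
  skip_if_not_installed("survival")
  trial <- feedback_trial(150, seed = 4)
  tab <- trial$table[trial$table$arm == 1, ]
  rec <- collapse_person_time(tab)
  # discretized time-to-event: event/censoring at the end of the last month
  time <- rec$max_followup_months
  status <- as.integer(!is.na(rec$death_month))
  sf <- survival::survfit(survival::Surv(time, status) ~ 1)
  cv <- km_curve(tab)
  at <- match(sf$time, cv$month)
  keep <- !is.na(at)
  expect_equal(cv$survival[at[keep]], sf$surv[keep], tolerance = 1e-12)

  set.seed(2)
  w_subj <- runif(nrow(rec), 0.5, 2)
  sfw <- survival::survfit(survival::Surv(time, status) ~ 1,
                           weights = w_subj)
  wvec <- w_subj[match(tab$subject_id, rec$subject_id)]
  cvw <- km_curve(tab, wvec)
  atw <- match(sfw$time, cvw$month)
  keepw <- !is.na(atw)
  expect_equal(cvw$survival[atw[keepw]], sfw$surv[keepw], tolerance = 1e-9)
})

test_that("pooled logistic degenerate and saturated fits behave as counted", {
  trial <- feedback_trial(150, seed = 4)
  tab <- trial$table

  # intercept-only: hazard = total deaths / total person-intervals
  fit0 <- fit_pooled_logistic(tab, "outcome", list())
  expect_equal(unname(plogis(fit0$coef[1])),
               sum(tab$outcome) / nrow(tab), tolerance = 1e-8)

  # saturated step function in time reproduces per-month count ratios
  tab$kf <- tab$k + 1
  months_with_both <- as.numeric(names(which(
    tapply(tab$outcome, tab$kf, function(y) any(y == 1) && any(y == 0)))))
  sat <- tab[tab$kf %in% months_with_both, ]
  sat$kf <- match(sat$kf, sort(unique(sat$kf)))
  fit_sat <- fit_pooled_logistic(
    sat, "outcome",
    list(term_spec("kf", "categorical", n_levels = max(sat$kf))))
  ph <- predict_hazard(fit_sat, sat)
  direct <- tapply(sat$outcome, sat$kf, mean)
  expect_equal(unname(tapply(ph, sat$kf, mean)), unname(direct),
               tolerance = 1e-6)

  # all outcomes zero: flagged, never silently plausible coefficients
  z <- tab[1:200, ]; z$outcome <- 0
  fitz <- fit_pooled_logistic(z, "outcome", term_list(k = "linear"))
  expect_true(!fitz$converged || fitz$separated)
})

test_that("km_curve equals curve_from_fit under a saturated-time model", {
  trial <- feedback_trial(150, seed = 4)
  tab <- trial$table[trial$table$arm == 1, ]
  # restrict to months with at-risk person-time (all, by construction)
  tab$kf <- tab$k + 1
  K <- max(tab$kf)
  fit <- fit_pooled_logistic(
    tab, "outcome", list(term_spec("kf", "categorical", n_levels = K)))
  km <- km_curve(tab)
  grid <- data.frame(kf = 1:K)
  h <- predict_hazard(fit, grid)
  expect_equal(h, km$hazard, tolerance = 1e-7)
  expect_equal(cumprod(1 - h), km$survival, tolerance = 1e-7)
})

test_that("standardized curves average risks, not hazards", {
  trial <- feedback_trial(150, seed = 4)
  tab <- trial$table
  tab$ecog_cat <- tab$ecog + 1
  fit <- fit_pooled_logistic(
    tab, "outcome",
    c(term_list(arm = "linear", k = "quadratic", age = "linear"),
      list(term_spec("ecog_cat", "categorical", n_levels = 3))))
  base <- tab[tab$k == 0, ]
  base$arm <- 1
  horizon <- 24
  std <- curve_from_fit(fit, base, horizon)

  # per-subject loop oracle
  risks <- sapply(seq_len(nrow(base)), function(i) {
    prof <- base[i, , drop = FALSE]
    grid <- prof[rep(1, horizon), ]
    grid$k <- 0:(horizon - 1)
    h <- predict_hazard(fit, grid)
    1 - cumprod(1 - h)
  })
  expect_equal(std$risk, rowMeans(risks), tolerance = 1e-10)

  # a model with arm as the only covariate: standardized = profile curve
  fit_arm <- fit_pooled_logistic(tab, "outcome",
                                 term_list(arm = "linear", k = "quadratic"))
  base1 <- tab[tab$k == 0, ]; base1$arm <- 0
  std1 <- curve_from_fit(fit_arm, base1, horizon)
  prof1 <- curve_from_fit(fit_arm, data.frame(arm = 0), horizon)
  expect_equal(std1$risk, prof1$risk, tolerance = 1e-12)
})

test_that("effect measures match closed-form evaluation", {
  flat <- function(h, K = 48) {
    structure(
      data.frame(month = 1:K, hazard = rep(h, K),
                 survival = cumprod(rep(1 - h, K)),
                 risk = 1 - cumprod(rep(1 - h, K)), n_risk = 100),
      class = c("survival_curve", "data.frame"))
  }
  ce <- flat(0.01); cc <- flat(0.02)
  est <- effect_estimates(cc, ce, horizon = 48)
  expect_equal(est$chr, log(0.99) / log(0.98), tolerance = 1e-12)
  expect_equal(est$rr, (1 - 0.99^48) / (1 - 0.98^48), tolerance = 1e-12)
  expect_equal(round(est$chr, 4), 0.4975)
  expect_equal(round(est$rr, 3), 0.616)

  # identical curves give 1; swapping arms inverts exactly
  expect_equal(effect_estimates(cc, cc, horizon = 48)$rr, 1)
  expect_equal(effect_estimates(cc, cc, horizon = 48)$chr, 1)
  swapped <- effect_estimates(ce, cc, horizon = 48)
  expect_equal(swapped$chr, 1 / est$chr, tolerance = 1e-12)
  expect_equal(swapped$rr, 1 / est$rr, tolerance = 1e-12)

  # sum-of-hazards alternative
  est2 <- effect_estimates(cc, ce, horizon = 48, chr_method = "sum_hazard")
  expect_equal(est2$chr, 0.5, tolerance = 1e-12)
})

test_that("dHR for rare events approximates the generator hazard ratio", {
  # constant rare hazards: treatment halves the death hazard
  cfg <- feedback_config()
  cfg$progression["intercept"] <- 20    # progression certain at month 0
  cfg$progression["treatment"] <- 0
  cfg$progression["tls10"] <- 0; cfg$progression["ecog"] <- 0
  cfg$death <- c(intercept = qlogis(0.008), treatment = log(0.5),
                 tls10 = 0, ecog = 0, tdp = 0, icp = 0, age10 = 0)
  cfg$switching["intercept"] <- -30
  cfg$censoring["intercept"] <- -30
  cfg$ecog_worsen["treatment"] <- 0; cfg$tls_drift["treatment"] <- 0
  cfg$n_control <- 2500; cfg$n_experimental <- 2500; cfg$seed <- 31
  suppressWarnings(trial <- generate_trial(cfg))
  fit <- fit_pooled_logistic(trial$table, "outcome",
                             term_list(arm = "linear", k = "quadratic"))
  dhr <- exp(unname(fit$coef["arm"]))
  expect_lt(abs(dhr - 0.5), 0.1)
})
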
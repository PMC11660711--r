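#' Synthetic two-arm trial generator
#'
#' Simulates individual-level cohorts from a discrete-time mechanism that
#' emulates the structure of a two-arm oncology trial with one-sided
#' crossover: monthly (30-day) intervals, progression-gated death, control
#' arm switching to the experimental drug only after disease progression,
#' pooled LTFU/administrative censoring, and treatment-confounder feedback
#' (prior treatment shifts target-lesion size and ECOG, which in turn drive
#' both switching and death).
#'
#' Within each month the update order is fixed: time-varying covariates
#' (ECOG, TLS, given the *previous* month's treatment and progression
#' state), then progression, then intracranial progression, then switching,
#' then censoring, then death (death takes precedence over same-interval
#' censoring). Switching takes effect in the interval it is drawn, so the
#' death hazard that month already reflects the new drug.
#'
#' Each subject consumes an RNG stream derived from `(seed, subject index)`
#' so cohorts are reproducible and stable under changes of `n`.
#'
#' @name synthetic_trial
NULL

#' Generator configuration
#'
#' All monthly hazards are logistic in the listed linear predictors;
#' `tls10` denotes `(TLS - 45)/10`. Structural zeros are enforced
#' regardless of coefficients: the switching hazard is 0 unless
#' `arm = 0`, progression has occurred and no switch has occurred yet, and
#' the death hazard is 0 before progression.
#'
#' @param n_control,n_experimental arm sizes (defaults 138 / 137).
#' @param horizon_months administrative horizon (default 48).
#' @param seed master seed for the per-subject streams.
#' @param baseline named list of baseline distribution parameters.
#' @param progression,switching,censoring,death,ecog_worsen,tls_drift named
#'   coefficient vectors of the monthly hazard / transition models.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_control = 138, n_experimental = 137,
                             horizon_months = 48, seed = 1,
                             baseline = list(), progression = c(),
                             switching = c(), censoring = c(), death = c(),
                             ecog_worsen = c(), tls_drift = c(), icp = c()) {
  def <- feedback_config()
  cfg <- def
  cfg$n_control <- n_control
  cfg$n_experimental <- n_experimental
  cfg$horizon_months <- horizon_months
  cfg$seed <- seed
  cfg$baseline <- utils::modifyList(def$baseline, baseline)
  for (nm in c("progression", "switching", "censoring", "death",
               "ecog_worsen", "tls_drift", "icp")) {
    v <- def[[nm]]
    upd <- get(nm)
    v[names(upd)] <- upd
    cfg[[nm]] <- v
  }
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_control >= 0, cfg$n_experimental >= 0,
            cfg$horizon_months >= 1)
  probs <- with(cfg$baseline, c(ecog_probs, smoking_probs, ids_probs,
                                li_probs, ics_p, race_p, sex_p,
                                brain_met_p, prior_chemo_p, rt_p))
  if (any(probs < 0 | probs > 1)) {
    stop_ppswitch("baseline probabilities must lie in [0, 1]")
  }
  if (expit(cfg$death["intercept"]) > 0.5 ||
      expit(cfg$progression["intercept"]) > 0.5) {
    warning("degenerate configuration: very large monthly hazards",
            call. = FALSE)
  }
  invisible(cfg)
}

#' Shipped feedback configuration
#'
#' The package's documented study conditions: 138/137 arms over 48 months;
#' the experimental drug delays progression (hazard ratio about 0.5 on the
#' logit scale), slows lesion growth and ECOG worsening, and roughly halves
#' the post-progression death hazard; switching in the control arm is
#' concentrated shortly after progression and strongly driven by lesion
#' size and ECOG (the treatment-confounder feedback channel that biases
#' censor-at-switch analyses); LTFU/AC is a small time-constant hazard. The
#' switching intercept is calibrated so that about 47% of control subjects
#' ever switch.
#'
#' @return a `generator_config`.
#' @export
feedback_config <- function() {
  structure(list(
    n_control = 138, n_experimental = 137, horizon_months = 48, seed = 1,
    baseline = list(
      age_mean = 58, age_sd = 11, age_range = c(25, 90),
      ecog_probs = c(0.39, 0.55, 0.06),
      ics_p = 0.17, race_p = 0.36, sex_p = 0.55,
      smoking_probs = c(0.55, 0.39, 0.06),
      brain_met_p = 0.29, prior_chemo_p = 0.27,
      ids_probs = c(0.06, 0.10, 0.09, 0.75),
      li_probs = c(0.25, 0.31, 0.35, 0.09),
      rt_p = 0.29,
      tls_meanlog = log(45), tls_sdlog = 0.50, tls_range = c(5, 250)),
    progression = c(intercept = -2.70, treatment = -0.30, tls10 = 0.12,
                    ecog = 0.25),
    switching  = c(intercept = -1.05, tdp = -0.70, tls10 = 0.05,
                   ecog = 0.30, ecog_tdp = -0.25, age10 = -0.60),
    censoring  = c(intercept = -5.50),
    death      = c(intercept = -6.10, treatment = -0.20, tls10 = 0.25,
                   ecog = 0.60, tdp = 0.01, icp = 0.30, age10 = 0.25),
    ecog_worsen = c(intercept = -3.60, treatment = -0.15, dp = 0.80),
    tls_drift   = c(intercept = 0.30, treatment = -0.50, dp = 1.20, sd = 3.0),
    icp = c(intercept = -4.00, dp = 0.80, ics = 0.50)),
    class = "generator_config")
}

#' Null configuration (treatment in no hazard or transition)
#'
#' Identical to [feedback_config()] with every treatment coefficient set to
#' zero; under it the two strategies share one counterfactual risk curve
#' and all estimators should recover RR = cHR = 1.
#'
#' @return a `generator_config`.
#' @export
null_config <- function() {
  cfg <- feedback_config()
  cfg$progression["treatment"] <- 0
  cfg$death["treatment"] <- 0
  cfg$ecog_worsen["treatment"] <- 0
  cfg$tls_drift["treatment"] <- 0
  cfg
}

draw_baseline <- function(b) {
  age <- min(max(stats::rnorm(1, b$age_mean, b$age_sd), b$age_range[1]),
             b$age_range[2])
  brain <- stats::rbinom(1, 1, b$brain_met_p)
  chemo <- stats::rbinom(1, 1, b$prior_chemo_p)
  list(age = age,
       ecog = sample(0:2, 1, prob = b$ecog_probs),
       ics = stats::rbinom(1, 1, b$ics_p),
       race = stats::rbinom(1, 1, b$race_p),
       sex = stats::rbinom(1, 1, b$sex_p),
       smoking = sample(1:3, 1, prob = b$smoking_probs),
       strata = 1L + brain + 2L * chemo,
       ids = sample(1:4, 1, prob = b$ids_probs),
       li = sample(1:4, 1, prob = b$li_probs),
       rt = stats::rbinom(1, 1, b$rt_p),
       tls0 = min(max(stats::rlnorm(1, b$tls_meanlog, b$tls_sdlog),
                      b$tls_range[1]), b$tls_range[2]))
}

# simulate one subject; intervene = NULL for the observed regime, or
# list(treatment = 0/1) forcing the strategy with switching and censoring
# hazards set to zero; collect_rows = FALSE skips row assembly (oracle use)
simulate_subject <- function(cfg, arm, intervene = NULL,
                             collect_rows = TRUE) {
  bl <- draw_baseline(cfg$baseline)
  K <- cfg$horizon_months
  forced <- !is.null(intervene)
  n <- K
  k_v <- 0:(K - 1)
  treatment <- dp <- icp <- switched <- outcome <- censored <- integer(n)
  ecog_tv <- numeric(n); tls <- numeric(n); tdp <- numeric(n)

  # hoist coefficient lookups out of the monthly loop
  cw <- cfg$ecog_worsen; cd <- cfg$tls_drift; cp <- cfg$progression
  cs <- cfg$switching; cdt <- cfg$death; ci <- cfg$icp
  p_cens <- expit(cfg$censoring[["intercept"]])

  # age enters hazards per decade from 58, plateauing below age 43 (the
  # youngest patients behave alike with respect to switching and death)
  age10 <- max((bl$age - 58) / 10, -1.5)
  prev_treat <- if (forced) intervene$treatment else arm
  prev_dp <- 0L; prev_icp <- 0L
  prev_ecog <- bl$ecog; prev_tls <- bl$tls0
  prog_month <- NA_integer_; sw_month <- NA_integer_
  cens_month <- NA_integer_; death_month <- NA_integer_
  cur_switched <- 0L
  last <- 0L

  for (k in seq_len(K) - 1L) {
    i <- k + 1L
    # 1) covariate update (skipped at k = 0: baseline values apply)
    if (k == 0L) {
      e <- bl$ecog; t <- bl$tls0
    } else {
      e <- prev_ecog
      if (e < 2 && stats::runif(1) < expit(
        cw[["intercept"]] + cw[["treatment"]] * prev_treat +
        cw[["dp"]] * prev_dp)) e <- e + 1
      t <- prev_tls + cd[["intercept"]] + cd[["treatment"]] * prev_treat +
        cd[["dp"]] * prev_dp + stats::rnorm(1, 0, cd[["sd"]])
      t <- max(t, 1)
    }
    tls10 <- (t - 45) / 10
    # 2) progression
    d <- prev_dp
    if (d == 0L) {
      p <- expit(cp[["intercept"]] + cp[["treatment"]] * prev_treat +
                 cp[["tls10"]] * tls10 + cp[["ecog"]] * e)
      if (stats::runif(1) < p) { d <- 1L; prog_month <- k }
    }
    td <- if (d == 1L) k - prog_month else 0
    # 3) intracranial progression
    ic <- prev_icp
    if (ic == 0L && stats::runif(1) < expit(
      ci[["intercept"]] + ci[["dp"]] * d + ci[["ics"]] * bl$ics)) {
      ic <- 1L
    }
    # 4) switching (control arm, post-progression, observed regime only)
    treat_k <- if (forced) intervene$treatment else prev_treat
    if (!forced && arm == 0L && d == 1L && cur_switched == 0L) {
      ps <- expit(cs[["intercept"]] + cs[["tdp"]] * td +
                  cs[["tls10"]] * tls10 + cs[["ecog"]] * e +
                  cs[["ecog_tdp"]] * e * td + cs[["age10"]] * age10)
      if (stats::runif(1) < ps) {
        cur_switched <- 1L; sw_month <- k; treat_k <- 1L
      }
    }
    # 5) censoring (observed regime only)
    cens_now <- !forced && stats::runif(1) < p_cens
    # 6) death, gated by progression; takes precedence over censoring
    die_now <- FALSE
    if (d == 1L) {
      pd <- expit(cdt[["intercept"]] + cdt[["treatment"]] * treat_k +
                  cdt[["tls10"]] * tls10 + cdt[["ecog"]] * e +
                  cdt[["tdp"]] * td + cdt[["icp"]] * ic +
                  cdt[["age10"]] * age10)
      die_now <- stats::runif(1) < pd
    }
    treatment[i] <- treat_k; dp[i] <- d; icp[i] <- ic
    ecog_tv[i] <- e; tls[i] <- t; tdp[i] <- td
    switched[i] <- cur_switched
    last <- i
    if (die_now) { outcome[i] <- 1L; death_month <- k; break }
    if (cens_now) { censored[i] <- 1L; cens_month <- k; break }
    prev_treat <- treat_k; prev_dp <- d; prev_icp <- ic
    prev_ecog <- e; prev_tls <- t
  }
  idx <- seq_len(last)
  rows <- if (collect_rows) {
    list(k = k_v[idx], treatment = treatment[idx], dp = dp[idx],
         icp = icp[idx], ecog_tv = ecog_tv[idx], tls = tls[idx],
         tdp = tdp[idx], outcome = outcome[idx], censored = censored[idx],
         switched = switched[idx])
  } else NULL
  list(rows = rows, n_rows = last, baseline = bl,
       progression_month = prog_month, switch_month = sw_month,
       censor_month = cens_month, death_month = death_month)
}

#' Generate a synthetic trial cohort
#'
#' Sequential monthly simulation per subject under the observed regime
#' (switching and censoring active). Identical configuration and seed give
#' byte-identical cohorts; subject `i`'s trajectory does not change when
#' the cohort is enlarged.
#'
#' @param config a `generator_config`.
#' @return list with `subjects` (subject table) and `table` (the
#'   corresponding `person_time` data frame).
#' @export
generate_trial <- function(config) {
  validate_generator_config(config)
  n <- config$n_control + config$n_experimental
  arms <- c(rep(0L, config$n_control), rep(1L, config$n_experimental))
  ids <- sprintf("S%04d", seq_len(n))
  sims <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subject_seed(config$seed, i))
    sims[[i]] <- simulate_subject(config, arms[i])
  }
  bls <- lapply(sims, `[[`, "baseline")
  num <- function(field) vapply(sims, function(s)
    if (is.na(s[[field]])) NA_real_ else as.numeric(s[[field]]), 0)
  subjects <- data.frame(
    subject_id = ids, arm = arms,
    progression_month = num("progression_month"),
    switch_month = num("switch_month"),
    censor_month = num("censor_month"),
    death_month = num("death_month"),
    max_followup_months = config$horizon_months,
    stringsAsFactors = FALSE)
  for (b in BASELINE_COLS) subjects[[b]] <- vapply(bls, `[[`, 0, b)
  n_rows <- vapply(sims, `[[`, 0L, "n_rows")
  table <- data.frame(
    subject_id = rep(ids, n_rows), k = integer(sum(n_rows)),
    arm = rep(arms, n_rows), stringsAsFactors = FALSE)
  for (v in c("k", "treatment", "dp", "icp", "ecog_tv", "tls", "tdp",
              "outcome", "censored", "switched")) {
    table[[v]] <- unlist(lapply(sims, function(s) s$rows[[v]]),
                         use.names = FALSE)
  }
  for (b in BASELINE_COLS) {
    table[[b]] <- rep(subjects[[b]], n_rows)
  }
  table <- table[, c(PT_COLS, BASELINE_COLS)]
  rownames(subjects) <- rownames(table) <- NULL
  class(table) <- c("person_time", "data.frame")
  list(subjects = subjects, table = table)
}

#' Oracle counterfactual risk by direct intervention on the generator
#'
#' Re-runs the generating mechanism with the switching and censoring
#' hazards forced to zero and treatment forced to the strategy's value at
#' every interval, and returns the empirical cumulative death risk per
#' month. This is the estimand's ground truth up to Monte-Carlo error of
#' order `sqrt(risk * (1 - risk) / n_oracle)`.
#'
#' @param config a `generator_config`.
#' @param strategy `"always_control"` or `"always_experimental"`.
#' @param n_oracle number of simulated histories (>= 1000).
#' @param seed RNG seed for the oracle streams (independent of the cohort).
#' @return object of class `counterfactual_truth`: data frame
#'   `(month, risk)` with attributes `strategy`, `n_oracle`, `mc_se`.
#' @export
simulate_truth <- function(config, strategy, n_oracle = 20000, seed = 2) {
  stopifnot(n_oracle >= 1000)
  a <- switch(strategy,
              always_control = 0L, always_experimental = 1L,
              stop_ppswitch(sprintf("unknown strategy '%s'", strategy)))
  K <- config$horizon_months
  death_month <- rep(NA_real_, n_oracle)
  for (i in seq_len(n_oracle)) {
    set.seed(subject_seed(seed, i))
    sim <- simulate_subject(config, arm = a, intervene = list(treatment = a),
                            collect_rows = FALSE)
    death_month[i] <- sim$death_month
  }
  risk <- vapply(1:K, function(m)
    mean(!is.na(death_month) & death_month <= m - 1), 0)
  structure(data.frame(month = 1:K, risk = risk),
            strategy = strategy, n_oracle = n_oracle,
            mc_se = sqrt(pmax(risk * (1 - risk), 1e-12) / n_oracle),
            class = c("counterfactual_truth", "data.frame"))
}

#' Read / write generator configurations as YAML
#' @param config a `generator_config`.
#' @param path file path.
#' @export
write_generator_config <- function(config, path) {
  out <- unclass(config)
  # named coefficient vectors must become YAML maps, not bare sequences
  for (nm in names(out)) {
    if (is.numeric(out[[nm]]) && !is.null(names(out[[nm]]))) {
      out[[nm]] <- as.list(out[[nm]])
    }
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_generator_config
#' @export
read_generator_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- feedback_config()
  for (nm in intersect(names(raw), names(cfg))) {
    if (nm == "baseline") {
      cfg$baseline <- utils::modifyList(cfg$baseline, raw$baseline)
    } else if (is.list(raw[[nm]]) || !is.null(names(raw[[nm]]))) {
      v <- cfg[[nm]]
      v[names(raw[[nm]])] <- unlist(raw[[nm]])
      cfg[[nm]] <- v
    } else {
      cfg[[nm]] <- raw[[nm]]
    }
  }
  validate_generator_config(cfg)
  cfg
}

#' Write a counterfactual truth curve as CSV
#' @param truth a `counterfactual_truth`.
#' @param path file path.
#' @export
write_truth_curve <- function(truth, path) {
  utils::write.csv(as.data.frame(truth), path, row.names = FALSE)
  invisible(path)
}
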
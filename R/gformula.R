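#' Parametric g-formula (noniterative conditional expectation)
#'
#' Fits pooled-over-time models for each time-varying covariate and for the
#' discrete death hazard within one randomized arm (each arm is analysed as
#' a separate observational study), then Monte-Carlo simulates covariate
#' and outcome histories under a sustained treatment strategy with
#' censoring eliminated. Deterministic restrictions are built in: disease
#' progression and intracranial progression are absorbing (their models are
#' fitted only where the covariate was 0 at the previous visit), and the
#' death hazard is structurally 0 before progression.
#'
#' Within each simulated month, covariates are updated in the order given
#' by the specification (default: ECOG, TLS, then progression, then
#' intracranial progression, mirroring the shipped generator's
#' within-month order), then treatment is set by the strategy (or drawn
#' from the fitted switching model under the natural course), then death is
#' drawn. Transition-type covariates (`increment`, `gaussian`) hold their
#' baseline value in month 0; hazard-type (`binary`) covariates can fire
#' from month 0 onward.
#'
#' @name gformula
NULL

#' G-formula covariate model description
#'
#' @param name covariate column name.
#' @param family `"binary"` (logistic hazard of becoming 1), `"increment"`
#'   (logistic probability of a +1 step while below `max_level`), or
#'   `"gaussian"` (pooled linear regression; simulated with the fitted
#'   maximum-likelihood residual SD, i.e. the root-mean-square residual).
#' @param terms list of [term_spec()] predictors; may reference baseline
#'   covariates, previously simulated same-interval covariates, lagged
#'   covariates (`lag_treatment`, `lag_dp`, `lag_icp`, `lag_ecog_tv`,
#'   `lag_tls`) and time `k`.
#' @param restrict `"absorbing"` (fit on rows where the lagged value is 0;
#'   stays 1 forever once 1) or `"none"`.
#' @param max_level ceiling for `increment` covariates (default 2).
#' @param lower lower clamp applied to simulated `gaussian` values
#'   (clamping is counted and reported).
#' @return a `gf_covariate` description.
#' @export
gf_covariate <- function(name,
                         family = c("binary", "increment", "gaussian"),
                         terms, restrict = c("none", "absorbing"),
                         max_level = 2, lower = -Inf) {
  family <- match.arg(family); restrict <- match.arg(restrict)
  structure(list(name = name, family = family, terms = terms,
                 restrict = restrict, max_level = max_level, lower = lower),
            class = "gf_covariate")
}

#' G-formula specification
#'
#' @param covariates ordered list of [gf_covariate()] descriptions; the
#'   order is the within-month simulation order.
#' @param outcome_terms predictor terms of the pooled logistic death-hazard
#'   model (fitted on post-progression person-time only).
#' @param treatment_terms predictor terms of the control-arm switching
#'   model, used only under the natural course.
#' @param n_sim number of Monte-Carlo histories (default 10000).
#' @param horizon months simulated (default 48).
#' @param label specification label.
#' @return a `gformula_spec`.
#' @export
gformula_spec <- function(covariates, outcome_terms,
                          treatment_terms = NULL, n_sim = 10000,
                          horizon = 48, label = "gformula") {
  structure(list(covariates = covariates, outcome_terms = outcome_terms,
                 treatment_terms = treatment_terms, n_sim = n_sim,
                 horizon = horizon, label = label),
            class = "gformula_spec")
}

#' Default specification mirroring the shipped generator
#'
#' ECOG worsening and TLS drift conditional on prior treatment and
#' progression, progression and intracranial progression hazards, and a
#' death model in current treatment, TLS, ECOG, time since progression and
#' intracranial status.
#'
#' @param n_sim,horizon passed through to [gformula_spec()].
#' @return a `gformula_spec`.
#' @export
default_gformula_spec <- function(n_sim = 10000, horizon = 48) {
  gformula_spec(
    covariates = list(
      gf_covariate("ecog_tv", "increment",
                   term_list(lag_treatment = "linear", lag_dp = "linear"),
                   max_level = 2),
      gf_covariate("tls", "gaussian",
                   term_list(lag_tls = "linear", lag_treatment = "linear",
                             lag_dp = "linear"),
                   lower = 1),
      gf_covariate("dp", "binary",
                   term_list(lag_treatment = "linear", tls = "linear",
                             ecog_tv = "linear"),
                   restrict = "absorbing"),
      gf_covariate("icp", "binary",
                   term_list(dp = "linear", ics = "linear"),
                   restrict = "absorbing")),
    outcome_terms = term_list(treatment = "linear", tls = "linear",
                              ecog_tv = "linear", tdp = "linear",
                              icp = "linear", age = "linear"),
    treatment_terms = c(term_list(age = "linear", tdp = "linear",
                                  tls = "linear", ecog_tv = "linear"),
                        list(term_spec("ecog_tv", "interaction",
                                       with = "tdp"))),
    n_sim = n_sim, horizon = horizon, label = "generator-faithful")
}

# drop terms whose variable is constant in the fitting subset (e.g. the
# treatment variable inside the experimental arm); returns list(terms, note)
drop_constant_terms <- function(data, terms) {
  keep <- vapply(terms, function(tm) {
    x <- data[[tm$variable]]
    if (identical(tm$transform, "interaction")) x <- x * data[[tm$with]]
    length(unique(x)) > 1
  }, TRUE)
  note <- if (all(keep)) "" else
    paste("dropped constant term(s):",
          paste(vapply(terms[!keep], `[[`, "", "variable"), collapse = ", "))
  list(terms = terms[keep], note = note)
}

fit_gaussian_model <- function(data, y_col, terms) {
  design <- design_build(data, terms)
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             design_matrix(design, data))
  fit <- stats::lm.fit(X, data[[y_col]])
  res <- fit$residuals
  structure(list(coef = fit$coefficients, sigma = sqrt(mean(res^2)),
                 design = design, n = nrow(X),
                 converged = !any(is.na(fit$coefficients))),
            class = "gaussian_fit")
}

predict_gaussian <- function(fit, newdata) {
  X <- cbind(rep(1, nrow(newdata)), design_matrix(fit$design, newdata))
  as.numeric(X %*% fit$coef)
}

#' Fit the g-formula model set for one arm
#'
#' @param table a `person_time` data frame (both arms; the requested arm is
#'   selected internally).
#' @param spec a [gformula_spec()].
#' @param arm 0 (control) or 1 (experimental).
#' @return object of class `gformula_models`; element `failed` is `TRUE`
#'   when any component model failed (consumed by the bootstrap as a
#'   replicate failure).
#' @export
fit_gformula_models <- function(table, spec, arm) {
  d <- table[table$arm == arm, ]
  if (!nrow(d)) stop_ppswitch("arm-restricted table is empty")
  d <- add_lagged_covariates(d)
  failed <- FALSE
  models <- list()
  for (cv in spec$covariates) {
    lag_col <- paste0("lag_", cv$name)
    # transition-type families describe month-to-month updates, so month-0
    # rows (which repeat the baseline value) carry no information
    sub <- switch(cv$family,
      binary = if (cv$restrict == "absorbing")
        d[d[[lag_col]] == 0, ] else d,
      increment = d[d$k >= 1 & d[[lag_col]] < cv$max_level, ],
      gaussian = d[d$k >= 1, ])
    entry <- list(cv = cv, skipped = FALSE, note = "")
    if (!nrow(sub)) {
      entry$skipped <- TRUE
      entry$note <- "no eligible person-time; value held fixed"
      models[[cv$name]] <- entry
      next
    }
    dct <- drop_constant_terms(sub, cv$terms)
    entry$note <- dct$note
    if (cv$family == "gaussian") {
      entry$fit <- fit_gaussian_model(sub, cv$name, dct$terms)
      if (!entry$fit$converged) failed <- TRUE
    } else {
      sub$.event <- if (cv$family == "binary") sub[[cv$name]] else
        as.integer(sub[[cv$name]] > sub[[paste0("lag_", cv$name)]])
      if (length(unique(sub$.event)) < 2) {
        # e.g. an absorbing covariate that is already 1 for everyone at
        # baseline: no model; simulate the constant event outcome
        entry$skipped <- TRUE
        entry$fixed_event <- sub$.event[1]
        entry$note <- "degenerate event column; constant event simulated"
        models[[cv$name]] <- entry
        next
      }
      entry$fit <- fit_pooled_logistic(sub, ".event", dct$terms)
      if (!entry$fit$converged) failed <- TRUE
    }
    models[[cv$name]] <- entry
  }
  # death model: post-progression person-time only (death gated on dp)
  at_risk <- d[d$dp == 1, ]
  outcome <- NULL
  if (nrow(at_risk) && any(at_risk$outcome == 1)) {
    dct <- drop_constant_terms(at_risk, spec$outcome_terms)
    outcome <- fit_pooled_logistic(at_risk, "outcome", dct$terms)
    if (!outcome$converged) failed <- TRUE
  } else failed <- TRUE
  # switching model for natural-course simulation (control arm only)
  treatment_model <- NULL
  if (arm == 0 && !is.null(spec$treatment_terms)) {
    sw <- switching_risk_set(d)
    if (nrow(sw) && any(sw$event == 1)) {
      dct <- drop_constant_terms(sw, spec$treatment_terms)
      treatment_model <- fit_pooled_logistic(sw, "event", dct$terms)
    }
  }
  structure(list(arm = arm, spec = spec, models = models, outcome = outcome,
                 treatment_model = treatment_model,
                 baseline_pool = d[d$k == 0, ], failed = failed),
            class = "gformula_models")
}

#' Simulate counterfactual histories from fitted g-formula models
#'
#' Draws `n_sim` baseline profiles by resampling the observed baseline rows
#' with replacement, then simulates covariates, treatment and death month
#' by month with treatment forced to the strategy value (`always_control`,
#' `always_experimental`) or drawn from the fitted switching model
#' (`natural_course`). Censoring is never simulated (the strategies enforce
#' complete follow-up). An automated audit verifies post hoc that the
#' intervention and restrictions held in the simulated data.
#'
#' @param models a `gformula_models` object.
#' @param strategy `"always_control"`, `"always_experimental"` or
#'   `"natural_course"`.
#' @param n_sim number of histories (defaults to the spec).
#' @param seed RNG seed.
#' @return object of class `gformula_result`: list with `risk` (data frame
#'   `month, risk, mc_se`), `covariate_means` (per-month means among the
#'   at-risk simulated histories), `audit`, `n_sim`, `n_clamped`,
#'   `strategy`.
#' @export
simulate_counterfactual <- function(models, strategy, n_sim = NULL,
                                    seed = 1) {
  strategy <- match.arg(strategy, c("always_control", "always_experimental",
                                    "natural_course"))
  if (models$failed) stop_ppswitch("g-formula models failed to fit")
  spec <- models$spec
  n <- n_sim %||% spec$n_sim
  K <- spec$horizon
  set.seed(seed)
  pool <- models$baseline_pool
  draw <- pool[sample(nrow(pool), n, replace = TRUE), , drop = FALSE]

  state <- data.frame(row.names = seq_len(n))
  for (b in intersect(c(BASELINE_COLS, "arm"), names(draw))) {
    state[[b]] <- draw[[b]]
  }
  # pre-baseline state: no progression, baseline ECOG / TLS, assigned drug
  prev <- list(dp = rep(0L, n), icp = rep(0L, n),
               ecog_tv = draw$ecog_tv, tls = draw$tls,
               treatment = rep(models$arm, n))
  forced <- switch(strategy, always_control = 0L, always_experimental = 1L,
                   natural_course = NULL)
  if (!is.null(forced)) prev$treatment <- rep(forced, n)

  alive <- rep(TRUE, n)
  prog_month <- rep(NA_real_, n)
  dead_month <- rep(NA_real_, n)
  n_clamped <- 0L
  absorbing_ok <- TRUE; gating_ok <- TRUE
  risk <- numeric(K)
  cov_means <- matrix(NA_real_, nrow = K, ncol = 5,
                      dimnames = list(NULL, c("dp", "icp", "ecog_tv", "tls",
                                              "at_risk")))
  sim_treat_min <- 1; sim_treat_max <- 0  # audit bookkeeping

  for (k in 0:(K - 1)) {
    cur <- state
    cur$k <- k
    cur$lag_treatment <- prev$treatment
    cur$lag_dp <- prev$dp; cur$lag_icp <- prev$icp
    cur$lag_ecog_tv <- prev$ecog_tv; cur$lag_tls <- prev$tls
    cur$dp <- prev$dp; cur$icp <- prev$icp
    cur$ecog_tv <- prev$ecog_tv; cur$tls <- prev$tls

    for (nm in names(models$models)) {
      entry <- models$models[[nm]]
      cv <- entry$cv
      if (entry$skipped) {
        fe <- entry$fixed_event
        if (!is.null(fe) && fe == 1 && cv$family == "binary") {
          cur[[nm]][alive & cur[[nm]] == 0] <- 1L
        }
        next
      }
      if (cv$family %in% c("increment", "gaussian") && k == 0) next
      if (cv$family == "binary") {
        todo <- alive & (if (cv$restrict == "absorbing")
          cur[[nm]] == 0 else rep(TRUE, n))
        if (any(todo)) {
          p <- predict_hazard(entry$fit, cur[todo, , drop = FALSE])
          cur[[nm]][todo] <- as.integer(stats::runif(sum(todo)) < p |
                                          cur[[nm]][todo] == 1)
        }
      } else if (cv$family == "increment") {
        todo <- alive & cur[[nm]] < cv$max_level
        if (any(todo)) {
          p <- predict_hazard(entry$fit, cur[todo, , drop = FALSE])
          cur[[nm]][todo] <- cur[[nm]][todo] +
            as.integer(stats::runif(sum(todo)) < p)
        }
      } else {
        todo <- alive
        if (any(todo)) {
          mu <- predict_gaussian(entry$fit, cur[todo, , drop = FALSE])
          val <- mu + stats::rnorm(sum(todo), 0, entry$fit$sigma)
          n_clamped <- n_clamped + sum(val < cv$lower)
          cur[[nm]][todo] <- pmax(val, cv$lower)
        }
      }
    }
    new_prog <- alive & cur$dp == 1 & is.na(prog_month)
    prog_month[new_prog] <- k
    cur$tdp <- ifelse(cur$dp == 1 & !is.na(prog_month), k - prog_month, 0)

    # treatment under the strategy / natural course
    if (!is.null(forced)) {
      cur$treatment <- rep(forced, n)
    } else {
      cur$treatment <- prev$treatment
      if (models$arm == 0 && !is.null(models$treatment_model)) {
        todo <- alive & cur$dp == 1 & prev$treatment == 0
        if (any(todo)) {
          p <- predict_hazard(models$treatment_model,
                              cur[todo, , drop = FALSE])
          sw <- stats::runif(sum(todo)) < p
          cur$treatment[todo][sw] <- 1L
        }
      }
    }
    sim_treat_min <- min(sim_treat_min, cur$treatment[alive], 1)
    sim_treat_max <- max(sim_treat_max, cur$treatment[alive], 0)

    # death, gated by progression
    todo <- alive & cur$dp == 1
    if (any(todo) && !is.null(models$outcome)) {
      p <- predict_hazard(models$outcome, cur[todo, , drop = FALSE])
      die <- stats::runif(sum(todo)) < p
      dead_month[which(todo)[die]] <- k
    }
    absorbing_ok <- absorbing_ok && all(cur$dp >= prev$dp) &&
      all(cur$icp >= prev$icp)
    gating_ok <- gating_ok && !any(!is.na(dead_month) &
                                     dead_month == k & cur$dp == 0)
    cov_means[k + 1, ] <- c(mean(cur$dp[alive]), mean(cur$icp[alive]),
                            mean(cur$ecog_tv[alive]), mean(cur$tls[alive]),
                            sum(alive))
    alive <- alive & is.na(dead_month)
    risk[k + 1] <- mean(!is.na(dead_month))
    prev <- list(dp = cur$dp, icp = cur$icp, ecog_tv = cur$ecog_tv,
                 tls = cur$tls, treatment = cur$treatment)
  }

  audit <- list(
    treatment_constant = is.null(forced) ||
      (sim_treat_min == forced && sim_treat_max == forced),
    risk_monotone = !is.unsorted(risk),
    absorbing_respected = absorbing_ok,
    death_gated_by_progression = gating_ok,
    no_censoring = TRUE)  # censoring is never simulated

  structure(list(
    strategy = strategy,
    risk = data.frame(month = 1:K, risk = risk,
                      mc_se = sqrt(pmax(risk * (1 - risk), 1e-12) / n)),
    covariate_means = data.frame(month = 1:K, cov_means),
    audit = audit, n_sim = n, n_clamped = n_clamped,
    label = spec$label),
    class = "gformula_result")
}

#' @export
print.gformula_result <- function(x, ...) {
  K <- nrow(x$risk)
  cat(sprintf("G-formula simulation: %s, %d histories (%s)\n",
              x$strategy, x$n_sim, x$label))
  cat(sprintf("  risk by month %d: %.3f (MC SE %.4f)\n",
              K, x$risk$risk[K], x$risk$mc_se[K]))
  if (x$n_clamped > 0) {
    cat(sprintf("  %d simulated continuous values clamped\n", x$n_clamped))
  }
  invisible(x)
}

#' Natural-course diagnostic
#'
#' Simulates the arm without intervention (treatment drawn from the fitted
#' switching model) and compares simulated covariate means and cumulative
#' death risk against the observed arm, month by month. A model set whose
#' natural course drifts from the observed data is misspecified.
#'
#' @param models a `gformula_models` object.
#' @param table the `person_time` data the models were fitted on.
#' @param n_sim histories (default 20000).
#' @param seed RNG seed.
#' @param tolerance absolute pass/fail tolerance applied to each
#'   (quantity, month) comparison; `mc_se` columns are returned so callers
#'   can apply Monte-Carlo-scaled criteria instead.
#' @return data frame with columns `month`, `quantity`, `simulated`,
#'   `observed`, `abs_diff`, `rel_diff`, `mc_se`, `pass`.
#' @export
natural_course_check <- function(models, table, n_sim = 20000, seed = 1,
                                 tolerance = 0.05) {
  res <- simulate_counterfactual(models, "natural_course", n_sim = n_sim,
                                 seed = seed)
  d <- table[table$arm == models$arm, ]
  K <- nrow(res$risk)
  obs_km <- km_curve(d)
  obs_risk <- rep(NA_real_, K)
  obs_risk[obs_km$month] <- obs_km$risk
  # carry the last defined observed risk forward if follow-up ends early
  for (m in seq_len(K)) if (is.na(obs_risk[m]) && m > 1) {
    obs_risk[m] <- obs_risk[m - 1]
  }
  rows <- list()
  for (q in c("dp", "icp", "ecog_tv", "tls")) {
    obs <- vapply(1:K, function(m) {
      x <- d[[q]][d$k == m - 1]
      if (length(x)) mean(x) else NA_real_
    }, 0)
    sim <- res$covariate_means[[q]]
    n_alive <- res$covariate_means$at_risk
    # MC SE of the simulated mean: binomial for the 0/1 covariates; the
    # continuous TLS mean gets NA (callers can use the observed spread)
    mc_se <- if (q == "tls") rep(NA_real_, K) else
      sqrt(pmax(sim * (1 - sim), 1e-12) / pmax(n_alive, 1))
    rows[[q]] <- data.frame(
      month = 1:K, quantity = q, simulated = sim, observed = obs,
      abs_diff = abs(sim - obs),
      rel_diff = ifelse(obs != 0, abs(sim - obs) / abs(obs), NA_real_),
      mc_se = mc_se, stringsAsFactors = FALSE)
  }
  rows$risk <- data.frame(
    month = 1:K, quantity = "risk", simulated = res$risk$risk,
    observed = obs_risk, abs_diff = abs(res$risk$risk - obs_risk),
    rel_diff = ifelse(obs_risk != 0,
                      abs(res$risk$risk - obs_risk) / obs_risk, NA_real_),
    mc_se = res$risk$mc_se, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$pass <- !is.na(out$abs_diff) & out$abs_diff <= tolerance
  out
}

#' Effect measures from two g-formula results
#'
#' @param result_control,result_experimental `gformula_result` objects
#'   sharing the horizon.
#' @param horizon effect horizon (default: full simulated horizon).
#' @param chr_method passed to [effect_estimates()].
#' @return an `effect_estimates` object.
#' @export
gformula_effects <- function(result_control, result_experimental,
                             horizon = NULL, chr_method = "neglog") {
  Kc <- nrow(result_control$risk); Ke <- nrow(result_experimental$risk)
  if (Kc != Ke) stop_ppswitch("results have mismatched horizons")
  horizon <- horizon %||% Kc
  as_curve <- function(res) {
    s <- 1 - res$risk$risk
    hz <- 1 - s / c(1, s[-length(s)])
    new_survival_curve(res$risk$month, hz, rep(res$n_sim, length(s)))
  }
  effect_estimates(as_curve(result_control), as_curve(result_experimental),
                   horizon = horizon, chr_method = chr_method)
}
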
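#' Analysis battery: ITT, naive per-protocol, and IPCW per-protocol
#'
#' Every estimator returns per-arm survival curves (Kaplan-Meier and pooled
#' logistic) plus [effect_estimates()]. The pooled logistic outcome model
#' uses the randomized arm and a quadratic polynomial in time by default;
#' alternative time parameterizations (e.g. a saturated step function) can
#' be supplied through `time_terms`.
#'
#' @name estimators
NULL

default_time_terms <- function() list(term_spec("k", "quadratic"))

# ITT baseline-adjustment covariate set: age, ECOG, intracranial CNS
# disease, race, sex, smoking, randomization strata, diagnosis stage, lung
# involvement, prior radiation
baseline_terms <- function() {
  list(term_spec("age", "linear"),
       term_spec("ecog_cat", "categorical", n_levels = 3),
       term_spec("ics", "linear"),
       term_spec("race", "linear"),
       term_spec("sex", "linear"),
       term_spec("smoking", "categorical", n_levels = 3),
       term_spec("strata", "categorical", n_levels = 4),
       term_spec("ids", "categorical", n_levels = 4),
       term_spec("li", "categorical", n_levels = 4),
       term_spec("rt", "linear"))
}

# categorical codes must start at 1; baseline ECOG is 0/1/2
prepare_analysis_table <- function(table) {
  if (!"ecog_cat" %in% names(table)) table$ecog_cat <- table$ecog + 1L
  table
}

fit_outcome_model <- function(table, adjust_terms = list(),
                              time_terms = default_time_terms(),
                              weights = NULL) {
  terms <- c(list(term_spec("arm", "linear")), time_terms, adjust_terms)
  fit_pooled_logistic(table, "outcome", terms, weights = weights)
}

arm_curves <- function(table, weights = NULL) {
  wvec <- if (is.null(weights)) NULL else resolve_weights(table, weights)
  pull <- function(a) {
    sel <- table$arm == a
    km_curve(table[sel, , drop = FALSE],
             if (is.null(wvec)) NULL else wvec[sel])
  }
  list(control = pull(0), experimental = pull(1))
}

model_curves <- function(fit, table, horizon, standardize = FALSE) {
  if (standardize) {
    base <- table[table$k == 0, , drop = FALSE]
    mk <- function(a) { d <- base; d$arm <- a; d }
  } else {
    mk <- function(a) data.frame(arm = a)
  }
  list(control = curve_from_fit(fit, mk(0), horizon),
       experimental = curve_from_fit(fit, mk(1), horizon))
}

finish_analysis <- function(approach, fit, km, pl, horizon, chr_method,
                            extra = list()) {
  hz <- min(horizon, max(km$control$month), max(km$experimental$month))
  out <- c(list(
    approach = approach,
    fit = fit,
    km = km, pooled = pl,
    effects_km = effect_estimates(km$control, km$experimental,
                                  horizon = hz, chr_method = chr_method),
    effects_pooled = effect_estimates(pl$control, pl$experimental, fit,
                                      horizon = horizon,
                                      chr_method = chr_method),
    horizon = horizon), extra)
  class(out) <- "ppswitch_analysis"
  out
}

#' @export
print.ppswitch_analysis <- function(x, ...) {
  cat(sprintf("Analysis: %s (horizon month %d)\n", x$approach, x$horizon))
  e <- x$effects_pooled
  cat(sprintf("  pooled logistic: dHR %.3f  cHR %.3f  RR %.3f\n",
              e$dhr, e$chr, e$rr))
  e <- x$effects_km
  cat(sprintf("  Kaplan-Meier:              cHR %.3f  RR %.3f\n",
              e$chr, e$rr))
  invisible(x)
}

#' Intention-to-treat analyses
#'
#' Four variants of the effect of treatment *assignment*:
#' * `"unadjusted"` — arm + quadratic time pooled logistic and KM;
#' * `"strata"` — adds randomization strata as categorical main effects;
#' * `"baseline"` — adds the full baseline covariate set (curves are
#'   conditional, evaluated at the control-arm reference profile);
#' * `"marginal"` — fits the baseline-adjusted model, then standardizes
#'   over baseline covariates by cloning every subject's baseline row once
#'   per assigned arm and averaging model-implied risks.
#'
#' @param table a `person_time` data frame.
#' @param variant one of `"unadjusted"`, `"strata"`, `"baseline"`,
#'   `"marginal"`.
#' @param horizon effect horizon in months (default 48).
#' @param weights optional LTFU/AC weight series, relaxing non-informative
#'   censoring.
#' @param time_terms time parameterization of the baseline hazard.
#' @param chr_method passed to [effect_estimates()].
#' @return a `ppswitch_analysis` object.
#' @export
itt_analysis <- function(table,
                         variant = c("unadjusted", "strata", "baseline",
                                     "marginal"),
                         horizon = 48, weights = NULL,
                         time_terms = default_time_terms(),
                         chr_method = "neglog") {
  variant <- match.arg(variant)
  table <- prepare_analysis_table(table)
  adjust <- switch(variant,
    unadjusted = list(),
    strata = list(term_spec("strata", "categorical", n_levels = 4)),
    baseline = baseline_terms(),
    marginal = baseline_terms())
  wvec <- if (is.null(weights)) NULL else resolve_weights(table, weights)
  fit <- fit_outcome_model(table, adjust, time_terms, weights = wvec)
  km <- arm_curves(table, weights)
  # adjusted variants report curves standardized over the observed baseline
  # table (the dHR stays conditional: the arm coefficient)
  pl <- model_curves(fit, table, horizon,
                     standardize = variant != "unadjusted")
  finish_analysis(paste0("itt_", variant), fit, km, pl, horizon, chr_method)
}

#' Naive per-protocol analyses
#'
#' `mode = "exclude"` drops all person-time of control subjects who ever
#' switched; `mode = "censor"` truncates switchers at the switch (the
#' switch interval itself is removed and no event is recorded there). Both
#' then run the unadjusted (or baseline-adjusted) ITT machinery. These
#' estimators are biased under treatment-confounder feedback and are
#' included as negative controls.
#'
#' @param table a `person_time` data frame.
#' @param mode `"exclude"` or `"censor"`.
#' @param adjust `"none"` or `"baseline"`.
#' @inheritParams itt_analysis
#' @return a `ppswitch_analysis` object.
#' @export
naive_pp <- function(table, mode = c("exclude", "censor"), adjust = "none",
                     horizon = 48, time_terms = default_time_terms(),
                     chr_method = "neglog") {
  mode <- match.arg(mode)
  check_columns(table, "switched", "person-time table")
  table <- prepare_analysis_table(table)
  ever <- unique(table$subject_id[table$switched == 1])
  d <- if (mode == "exclude") {
    table[!table$subject_id %in% ever, ]
  } else {
    sw_k <- stats::ave(ifelse(table$switched == 1, table$k, Inf),
                       table$subject_id, FUN = min)
    table[table$k < sw_k, ]
  }
  if (!nrow(d[d$arm == 0, ])) {
    stop_ppswitch("all control subjects switched: empty control arm")
  }
  adjust_terms <- if (identical(adjust, "baseline")) baseline_terms() else list()
  fit <- fit_outcome_model(d, adjust_terms, time_terms)
  km <- arm_curves(d)
  pl <- model_curves(fit, d, horizon,
                     standardize = length(adjust_terms) > 0)
  label <- if (mode == "exclude") "pp_exclude_switchers" else
    "pp_censor_at_switch"
  finish_analysis(label, fit, km, pl, horizon, chr_method)
}

#' IPCW per-protocol analysis
#'
#' The package's primary per-protocol estimator of the sustained strategies
#' "always treat with the experimental drug" versus "always treat with the
#' control drug": builds stabilized switching weights and LTFU/AC weights,
#' multiplies them, optionally truncates, censors person-time at the
#' minimum of switching and LTFU/AC, and fits the weighted outcome model —
#' randomized arm plus linear and quadratic time, *no confounders as
#' covariates* — together with the weighted KM.
#'
#' @param table a `person_time` data frame.
#' @param switch_spec [weight_spec()] for switching.
#' @param ltfu_spec optional [weight_spec()] for LTFU/AC; when `NULL` only
#'   switching weights are applied.
#' @param truncation optional `c(lower_pct, upper_pct)` percentile
#'   truncation of the combined weights.
#' @param stabilized use stabilized (default) or unstabilized weights.
#' @inheritParams itt_analysis
#' @return a `ppswitch_analysis` with extra elements `weights`
#'   (`weight_series`) and `diagnostics`.
#' @export
ipcw_pp_analysis <- function(table, switch_spec, ltfu_spec = NULL,
                             truncation = NULL, horizon = 48,
                             stabilized = TRUE,
                             time_terms = default_time_terms(),
                             chr_method = "neglog") {
  table <- prepare_analysis_table(table)
  sw_fits <- fit_weight_models(table, switch_spec)
  ws <- compute_weights(sw_fits, table)
  if (!is.null(ltfu_spec)) {
    lt_fits <- fit_weight_models(table, ltfu_spec)
    ws <- combine_weights(ws, compute_weights(lt_fits, table))
  }
  if (!is.null(truncation)) {
    ws <- truncate_weights(ws, truncation[1], truncation[2])
  }
  # person-time restricted to the weighted rows (up to min(switch, LTFU))
  key <- paste(table$subject_id, table$k)
  idx <- match(key, paste(ws$subject_id, ws$k))
  d <- table[!is.na(idx), ]
  wcol <- if (stabilized) "stabilized" else "unstabilized"
  wvec <- ws[[wcol]][idx[!is.na(idx)]]
  fit <- fit_outcome_model(d, adjust_terms = list(), time_terms,
                           weights = wvec)
  km <- arm_curves(d, wvec)
  pl <- model_curves(fit, d, horizon)
  finish_analysis("pp_ipcw", fit, km, pl, horizon, chr_method,
                  extra = list(weights = ws,
                               diagnostics = weight_diagnostics(ws)))
}
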
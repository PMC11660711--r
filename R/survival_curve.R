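#' Discrete-time survival curves
#'
#' A `survival_curve` tabulates, on the monthly grid `1..K` (month `m`
#' covers interval `k = m - 1`), the discrete hazard `h_m`, the
#' product-limit survival `S_m = prod(1 - h)` and the cumulative risk
#' `1 - S_m`, together with the (possibly weighted) at-risk mass.
#'
#' @name survival_curve
NULL

new_survival_curve <- function(month, hazard, n_risk, weighted = FALSE,
                               truncated = FALSE) {
  surv <- cumprod(1 - hazard)
  structure(
    data.frame(month = month, hazard = hazard, survival = surv,
               risk = 1 - surv, n_risk = n_risk),
    weighted = weighted, truncated = truncated,
    class = c("survival_curve", "data.frame"))
}

# resolve a weights argument (weight series data frame or numeric vector)
# into a per-row vector aligned with `table`
resolve_weights <- function(table, weights) {
  if (is.null(weights)) return(rep(1, nrow(table)))
  if (is.numeric(weights)) {
    if (length(weights) != nrow(table)) {
      stop_ppswitch("numeric weights misaligned with person-time rows")
    }
    return(weights)
  }
  check_columns(weights, c("subject_id", "k", "stabilized"), "weight series")
  key <- paste(table$subject_id, table$k)
  idx <- match(key, paste(weights$subject_id, weights$k))
  if (anyNA(idx)) {
    stop_ppswitch("weight series does not cover all person-time rows")
  }
  weights$stabilized[idx]
}

#' Life-table (Kaplan-Meier) curve from person-time
#'
#' The discrete hazard at month `m` is the (weighted) number of deaths in
#' interval `k = m - 1` divided by the (weighted) mass at risk entering the
#' interval; the unweighted case is the Kaplan-Meier estimator on the
#' discretized data. Subjects censored in an interval count as at risk
#' during it (standard life-table convention).
#'
#' @param table person-time rows for one group (e.g. one arm).
#' @param weights optional weight series (see [compute_weights()]) or
#'   numeric per-row vector; stabilized weights are used.
#' @return a `survival_curve`. If the at-risk mass hits zero before the last
#'   observed month, the curve is truncated there and flagged.
#' @export
km_curve <- function(table, weights = NULL) {
  check_columns(table, c("k", "outcome"), "person-time table")
  w <- resolve_weights(table, weights)
  kmax <- max(table$k)
  f <- factor(table$k, levels = 0:kmax)
  group_sum <- function(x) {
    out <- tapply(x, f, sum)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  at_risk <- group_sum(w)
  deaths <- group_sum(w * table$outcome)
  truncated <- FALSE
  if (any(at_risk <= 0)) {
    cut <- which(at_risk <= 0)[1] - 1
    if (cut == 0) stop_ppswitch("no person-time at risk in month 1")
    at_risk <- at_risk[1:cut]; deaths <- deaths[1:cut]
    truncated <- TRUE
  }
  hz <- deaths / at_risk
  new_survival_curve(seq_along(hz), hz, at_risk,
                     weighted = !is.null(weights), truncated = truncated)
}

#' Survival curve implied by a pooled logistic fit
#'
#' For a single covariate profile, predicts the hazard at each month and
#' cumulates it. For a standardization table (e.g. the cloned baseline
#' copies of the marginal ITT analysis), predicts per-subject hazards,
#' cumulates per subject, and averages the *risks* — not the hazards —
#' across subjects.
#'
#' The fit's time variable is looked up by name (`time_var`, default
#' `"k"`); it is set to `0..horizon-1` and must not be present in
#' `profile`.
#'
#' @param fit a converged `pooled_logistic` outcome-model fit.
#' @param profile one-row data frame (conditional curve) or many-row
#'   standardization table.
#' @param horizon number of months.
#' @param time_var name of the interval-index variable in the fit.
#' @return a `survival_curve` (model-based, at-risk mass = number of
#'   profiles).
#' @export
curve_from_fit <- function(fit, profile, horizon, time_var = "k") {
  if (!fit$converged) stop_ppswitch("outcome-model fit did not converge")
  n <- nrow(profile)
  grid <- profile[rep(seq_len(n), each = horizon), , drop = FALSE]
  grid[[time_var]] <- rep(0:(horizon - 1), times = n)
  h <- matrix(predict_hazard(fit, grid), nrow = horizon)
  surv <- apply(1 - h, 2, cumprod)
  surv <- matrix(surv, nrow = horizon)
  mean_risk <- rowMeans(1 - surv)
  # express the averaged risk back as a hazard sequence
  s_bar <- 1 - mean_risk
  hz <- 1 - s_bar / c(1, s_bar[-horizon])
  new_survival_curve(1:horizon, hz, rep(n, horizon))
}

#' Effect measures from two survival curves
#'
#' Computes, by the stated horizon month:
#' * `rr` — ratio of cumulative risks, experimental over control;
#' * `chr` — cumulative hazard ratio, by default the ratio of
#'   `-log S(horizon)` (method `"neglog"`); the discrete alternative
#'   `sum(h_m)` ratio is available as method `"sum_hazard"`;
#' * `dhr` — discrete hazard ratio `exp(arm coefficient)` when a pooled
#'   logistic fit containing an arm term is supplied.
#'
#' @param curve_control,curve_experimental `survival_curve` objects defined
#'   through `horizon`.
#' @param fit optional `pooled_logistic` fit carrying an `arm_term`
#'   coefficient.
#' @param horizon month at which measures are evaluated (default 48).
#' @param chr_method `"neglog"` or `"sum_hazard"`.
#' @param arm_term coefficient label for the randomized-arm indicator.
#' @return an object of class `effect_estimates`: list with `dhr`, `chr`,
#'   `rr`, `horizon`, `chr_method`, `undefined` flag.
#' @export
effect_estimates <- function(curve_control, curve_experimental, fit = NULL,
                             horizon = 48,
                             chr_method = c("neglog", "sum_hazard"),
                             arm_term = "arm") {
  chr_method <- match.arg(chr_method)
  pick <- function(cv) {
    if (max(cv$month) < horizon) {
      stop_ppswitch("curve not defined through the requested horizon")
    }
    cv[cv$month <= horizon, ]
  }
  cc <- pick(curve_control); ce <- pick(curve_experimental)
  risk_c <- cc$risk[horizon]; risk_e <- ce$risk[horizon]
  undefined <- risk_c <= 0 || cc$survival[horizon] >= 1
  rr <- if (undefined) NA_real_ else risk_e / risk_c
  chr <- if (undefined) NA_real_ else if (chr_method == "neglog") {
    -log(ce$survival[horizon]) / -log(cc$survival[horizon])
  } else {
    sum(ce$hazard) / sum(cc$hazard)
  }
  dhr <- NA_real_
  if (!is.null(fit) && arm_term %in% names(fit$coef)) {
    dhr <- exp(unname(fit$coef[arm_term]))
  }
  structure(list(dhr = dhr, chr = chr, rr = rr, horizon = horizon,
                 chr_method = chr_method, undefined = undefined),
            class = "effect_estimates")
}

#' @export
print.effect_estimates <- function(x, ...) {
  cat(sprintf("Effect measures by month %d (cHR method: %s)\n",
              x$horizon, x$chr_method))
  cat(sprintf("  dHR %.3f  cHR %.3f  RR %.3f%s\n", x$dhr, x$chr, x$rr,
              if (x$undefined) "  [undefined ratio flagged]" else ""))
  invisible(x)
}

#' Write a survival curve as CSV
#' @param curve a `survival_curve`.
#' @param path file path.
#' @export
write_survival_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}
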
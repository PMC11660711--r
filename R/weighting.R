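#' Inverse probability of censoring weights
#'
#' IPCW treats a protocol deviation (crossover to the experimental drug, or
#' LTFU/administrative censoring) as an artificial censoring event: person-
#' time at and after the event is removed, and the remaining comparable
#' person-time is up-weighted by the inverse of the modelled probability of
#' having remained event-free, forming a pseudo-population in which the
#' deviation is independent of the measured covariates.
#'
#' Deterministic knowledge enters as weight-of-1 rules: experimental-arm
#' subjects cannot switch (one-sided crossover), and control subjects
#' cannot switch before disease progression, so their switching weight is 1
#' at every such interval. The non-deterministic switching models are
#' fitted on control-arm post-progression person-time only.
#'
#' @name weighting
NULL

#' Weighting-model specification
#'
#' @param event `"switching"` or `"ltfu_ac"`.
#' @param denominator list of [term_spec()] covariate terms of the
#'   denominator (covariate-conditional) model.
#' @param numerator list of time-only terms for the stabilization
#'   numerator (default: linear follow-up time `k`).
#' @param denominator_experimental optional distinct denominator term list
#'   for the experimental arm (`ltfu_ac` only; arm-specific covariate
#'   sets).
#' @param label free-text specification label (e.g. `"switch-spec-4"`).
#' @return object of class `weight_spec`.
#' @export
weight_spec <- function(event = c("switching", "ltfu_ac"), denominator,
                        numerator = list(term_spec("k", "linear")),
                        denominator_experimental = NULL,
                        label = NULL) {
  event <- match.arg(event)
  time_ok <- vapply(numerator, function(tm)
    tm$variable == "k" && tm$transform %in% c("linear", "spline5"), TRUE)
  if (!all(time_ok)) {
    stop_ppswitch("numerator terms must be functions of time only")
  }
  structure(list(
    event = event, denominator = denominator, numerator = numerator,
    denominator_experimental = denominator_experimental,
    restrict_to_post_progression = event == "switching",
    label = label %||% event),
    class = "weight_spec")
}

# person-time eligible to the switching models, with the event indicator:
# control arm, post-progression, up to and including the first switch row
switching_risk_set <- function(table) {
  d <- table[table$arm == 0 & table$dp == 1, ]
  if (!nrow(d)) return(d)
  d <- d[order(d$subject_id, d$k), ]
  sw_first <- stats::ave(d$switched, d$subject_id,
                         FUN = function(s) cumsum(cumsum(s)) <= 1)
  d <- d[sw_first == 1, ]
  d$event <- d$switched
  d
}

ltfu_risk_set <- function(table, arm) {
  d <- table[table$arm == arm, ]
  d$event <- d$censored
  d
}

#' Fit numerator / denominator weighting models
#'
#' Pooled logistic models of the event hazard. Switching models are fitted
#' to control-arm post-progression person-time; LTFU/AC models are fitted
#' separately in each arm. A positivity red flag is raised when any fitted
#' event probability exceeds 0.99.
#'
#' @param table a `person_time` data frame.
#' @param spec a [weight_spec()].
#' @return object of class `weight_fits`: per-arm numerator/denominator
#'   `pooled_logistic` fits plus the spec.
#' @export
fit_weight_models <- function(table, spec) {
  fit_pair <- function(d, den_terms) {
    if (!nrow(d)) stop_ppswitch("empty eligible person-time for weight model")
    if (!any(d$event == 1)) {
      return(list(num = NULL, den = NULL, failed = TRUE,
                  reason = "no events in eligible person-time"))
    }
    den <- fit_pooled_logistic(d, "event", den_terms)
    num <- fit_pooled_logistic(d, "event", spec$numerator)
    positivity_flag <- any(predict_hazard(den, d) > 0.99)
    list(num = num, den = den, failed = !den$converged || !num$converged,
         positivity_flag = positivity_flag)
  }
  fits <- if (spec$event == "switching") {
    d <- switching_risk_set(table)
    if (!nrow(d)) {
      stop_ppswitch("no control-arm post-progression person-time: switching weights undefined")
    }
    list(control = fit_pair(d, spec$denominator))
  } else {
    list(control = fit_pair(ltfu_risk_set(table, 0L), spec$denominator),
         experimental = fit_pair(
           ltfu_risk_set(table, 1L),
           spec$denominator_experimental %||% spec$denominator))
  }
  structure(list(spec = spec, fits = fits), class = "weight_fits")
}

#' Compute stabilized and unstabilized weight series
#'
#' For each subject and retained interval `k`, the stabilized weight is the
#' cumulative product over eligible intervals `m <= k` of
#' `(1 - p_num(m)) / (1 - p_den(m))`, and the unstabilized weight the
#' product of `1 / (1 - p_den(m))`; intervals under a deterministic rule
#' contribute a factor of 1. Person-time at and after the event is excluded
#' (the subject is censored there), so weights are non-anticipating: the
#' weight at `k` depends only on data through `k`.
#'
#' @param fits a `weight_fits` object.
#' @param table the `person_time` data the fits were built from.
#' @param spec the matching [weight_spec()] (defaults to the one in
#'   `fits`).
#' @return object of class `weight_series`: data frame
#'   `(subject_id, k, stabilized, unstabilized)` with a `diagnostics`
#'   attribute ([weight_diagnostics()]).
#' @export
compute_weights <- function(fits, table, spec = fits$spec) {
  d <- table[order(table$subject_id, table$k), ]
  n <- nrow(d)
  p_den <- numeric(n); p_num <- numeric(n)   # 0 => deterministic factor 1
  drop_row <- logical(n)

  mark_arm <- function(rows, pair) {
    if (is.null(pair$den)) {
      stop_ppswitch("weight models failed; cannot compute weights")
    }
    p_den[rows] <<- predict_hazard(pair$den, d[rows, ])
    p_num[rows] <<- predict_hazard(pair$num, d[rows, ])
  }

  if (spec$event == "switching") {
    # eligible: control, post-progression, before the switch event
    sw_k <- stats::ave(ifelse(d$switched == 1, d$k, Inf), d$subject_id,
                       FUN = min)
    eligible <- d$arm == 0 & d$dp == 1 & d$k < sw_k
    drop_row <- d$k >= sw_k          # switch interval and later removed
    if (any(eligible)) mark_arm(which(eligible), fits$fits$control)
  } else {
    cens_k <- stats::ave(ifelse(d$censored == 1, d$k, Inf), d$subject_id,
                         FUN = min)
    eligible <- d$k < cens_k
    drop_row <- d$k >= cens_k
    for (a in c(0L, 1L)) {
      rows <- which(eligible & d$arm == a)
      pair <- if (a == 0L) fits$fits$control else fits$fits$experimental
      if (length(rows)) mark_arm(rows, pair)
    }
  }
  if (any(p_den[!drop_row] >= 1)) {
    bad <- which(p_den >= 1 & !drop_row)[1]
    stop_ppswitch(sprintf(
      "infinite weight: event-free probability 0 for subject %s interval %d",
      d$subject_id[bad], d$k[bad]))
  }
  log_fac_st <- log1p(-p_num) - log1p(-p_den)
  log_fac_un <- -log1p(-p_den)
  st <- exp(stats::ave(log_fac_st, d$subject_id, FUN = cumsum))
  un <- exp(stats::ave(log_fac_un, d$subject_id, FUN = cumsum))
  out <- data.frame(subject_id = d$subject_id, k = d$k,
                    stabilized = st, unstabilized = un,
                    stringsAsFactors = FALSE)[!drop_row, ]
  rownames(out) <- NULL
  new_weight_series(out)
}

new_weight_series <- function(df) {
  structure(df, diagnostics = weight_diagnostics_raw(df$stabilized),
            class = c("weight_series", "data.frame"))
}

#' Elementwise product of two weight series
#'
#' Combines e.g. switching and LTFU/AC weights; person-time is restricted
#' to the intersection (all observations up to the minimum of the two
#' censoring events), and diagnostics are recomputed.
#'
#' @param a,b `weight_series` objects.
#' @return a `weight_series`.
#' @export
combine_weights <- function(a, b) {
  key_a <- paste(a$subject_id, a$k); key_b <- paste(b$subject_id, b$k)
  idx <- match(key_a, key_b)
  keep <- !is.na(idx)
  out <- data.frame(subject_id = a$subject_id[keep], k = a$k[keep],
                    stabilized = a$stabilized[keep] * b$stabilized[idx[keep]],
                    unstabilized = a$unstabilized[keep] * b$unstabilized[idx[keep]],
                    stringsAsFactors = FALSE)
  new_weight_series(out)
}

#' Percentile truncation of weights
#'
#' Clips both weight variants to the empirical `[lower_pct, upper_pct]`
#' percentiles of their own pooled person-time distribution. `(0, 100)`
#' leaves the weights unchanged; `(50, 50)` collapses every weight to the
#' median, which makes any downstream weighted analysis numerically equal
#' to its unweighted counterpart.
#'
#' @param ws a `weight_series`.
#' @param lower_pct,upper_pct percentile bounds in `[0, 100]`.
#' @return a truncated `weight_series`.
#' @export
truncate_weights <- function(ws, lower_pct, upper_pct) {
  stopifnot(lower_pct >= 0, upper_pct <= 100,
            lower_pct < upper_pct || (lower_pct == 50 && upper_pct == 50))
  clip <- function(w) {
    q <- stats::quantile(w, probs = c(lower_pct, upper_pct) / 100,
                         names = FALSE, type = 7)
    pmin(pmax(w, q[1]), q[2])
  }
  out <- as.data.frame(ws)
  out$stabilized <- clip(out$stabilized)
  out$unstabilized <- clip(out$unstabilized)
  new_weight_series(out)
}

weight_diagnostics_raw <- function(w) {
  list(mean = mean(w), sd = stats::sd(w), min = min(w), max = max(w),
       n = length(w))
}

#' Weight diagnostics
#'
#' Mean, SD, min and max of the stabilized weights over person-time, with
#' an extreme-weight alarm raised when the mean drifts from 1 beyond
#' `mean_tol` or the maximum exceeds `max_mult` times the mean (the
#' signature of an unstable weighting-model specification).
#'
#' @param ws a `weight_series`.
#' @param mean_tol tolerated deviation of the mean from 1 (default 0.1).
#' @param max_mult tolerated max / mean ratio (default 10).
#' @return object of class `weight_diagnostics` (list with `mean`, `sd`,
#'   `min`, `max`, `n`, `flag_mean`, `flag_max`).
#' @export
weight_diagnostics <- function(ws, mean_tol = 0.1, max_mult = 10) {
  stopifnot(nrow(ws) > 0)
  dg <- weight_diagnostics_raw(ws$stabilized)
  dg$flag_mean <- abs(dg$mean - 1) > mean_tol
  dg$flag_max <- dg$max > max_mult * dg$mean
  class(dg) <- "weight_diagnostics"
  dg
}

#' @export
print.weight_diagnostics <- function(x, ...) {
  cat(sprintf("Stabilized weights over %d person-intervals\n", x$n))
  cat(sprintf("  Mean (SD): %s (%s)   Min (Max): %s (%s)\n",
              fmt_est(x$mean), fmt_est(x$sd), fmt_est(x$min),
              fmt_est(x$max)))
  if (x$flag_mean) cat("  ** mean deviates from 1 **\n")
  if (x$flag_max) cat("  ** extreme maximum weight **\n")
  invisible(x)
}

#' Univariate covariate screening for weighting models
#'
#' Screens each candidate term with a univariate pooled logistic model of
#' the event: a term is retained when its likelihood-ratio p-value is at or
#' below `p_max` (0.20) or any of its odds ratios falls outside
#' `[or_low, or_high]` (`[0.75, 1.33]`). AIC is reported alongside.
#' Non-estimable candidates (constant columns) are skipped with a note.
#'
#' @param table eligible person-time rows.
#' @param candidates list of [term_spec()] candidates.
#' @param event_col event column name.
#' @param p_max,or_low,or_high selection thresholds.
#' @return data frame, one row per candidate in input order, with columns
#'   `variable`, `transform`, `p_value`, `or_min`, `or_max`, `aic`,
#'   `selected`, `note`.
#' @export
screen_covariates <- function(table, candidates, event_col,
                              p_max = 0.20, or_low = 0.75, or_high = 1.33) {
  stopifnot(length(candidates) > 0)
  rows <- lapply(candidates, function(tm) {
    base <- data.frame(variable = tm$variable, transform = tm$transform,
                       p_value = NA_real_, or_min = NA_real_,
                       or_max = NA_real_, aic = NA_real_, selected = FALSE,
                       note = "", stringsAsFactors = FALSE)
    if (length(unique(table[[tm$variable]])) < 2) {
      base$note <- "skipped: constant column"
      return(base)
    }
    fit <- tryCatch(fit_pooled_logistic(table, event_col, list(tm)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      base$note <- "skipped: not estimable"
      return(base)
    }
    ors <- exp(fit$coef[-1])
    base$p_value <- pooled_logistic_pvalue(fit)
    base$or_min <- min(ors); base$or_max <- max(ors)
    base$aic <- fit$aic
    base$selected <- (!is.na(base$p_value) && base$p_value <= p_max) ||
      base$or_min < or_low || base$or_max > or_high
    base
  })
  do.call(rbind, rows)
}

#' Write a weight series / its diagnostics as CSV
#' @param ws a `weight_series`.
#' @param path file path.
#' @export
write_weight_series <- function(ws, path) {
  utils::write.csv(as.data.frame(ws), path, row.names = FALSE)
  invisible(path)
}
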
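#' Pooled logistic regression for discrete-time hazards
#'
#' Fits a maximum-likelihood logistic model for a binary event indicator
#' over person-intervals (pooled over time), the discrete-time analogue of
#' a proportional-hazards fit. Rows must already be restricted to the
#' at-risk set (no rows after a prior event); person-time produced by
#' [expand_to_person_time()] or [generate_trial()] satisfies this. Supports
#' per-row weights (IPC-weighted outcome models); with non-integer weights
#' the fit is the weighted-likelihood estimator.
#'
#' Convergence is reported honestly: `converged = FALSE` on IRLS
#' non-convergence, and `separated = TRUE` when coefficients diverge or
#' fitted probabilities pin to 0/1 (complete separation). Downstream
#' bootstrap treats either as a replicate failure.
#'
#' @param data person-time rows (the at-risk set).
#' @param outcome name of the binary event column.
#' @param terms list of [term_spec()] covariate terms (intercept added
#'   automatically).
#' @param weights optional non-negative per-row weights.
#' @param design optional pre-built `design_ref` (prediction-time reuse).
#' @return an object of class `pooled_logistic` with elements `coef`,
#'   `vcov`, `converged`, `separated`, `n`, `design`, `outcome`.
#' @export
fit_pooled_logistic <- function(data, outcome, terms, weights = NULL,
                                design = NULL) {
  check_columns(data, outcome, "fitting data")
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop_ppswitch("outcome column must be binary 0/1")
  if (is.null(design)) design <- design_build(data, terms)
  X <- cbind(`(Intercept)` = rep(1, nrow(data)),
             design_matrix(design, data))
  w <- if (is.null(weights)) rep(1, nrow(X)) else as.numeric(weights)
  if (length(w) != nrow(X)) stop_ppswitch("weights misaligned with rows")
  if (any(w < 0)) stop_ppswitch("negative weights")

  fit <- withCallingHandlers(
    stats::glm.fit(X, y, weights = w, family = stats::binomial()),
    warning = function(wn) {
      # these conditions are reported through the converged/separated flags
      if (grepl("non-integer|fitted probabilities|did not converge",
                conditionMessage(wn))) {
        invokeRestart("muffleWarning")
      }
    })
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  mu <- fit$fitted.values
  separated <- any(abs(coefs[!aliased]) > 15) ||
    (any(y == 1) && all(mu[y == 1] > 1 - 1e-8) && all(mu[y == 0] < 1e-8))
  info_w <- w * mu * (1 - mu)
  vc <- tryCatch({
    Xk <- X[, !aliased, drop = FALSE]
    solve(crossprod(Xk * sqrt(info_w)))
  }, error = function(e) NULL)
  converged <- isTRUE(fit$converged) && !any(aliased) && !is.null(vc)

  structure(list(
    coef = coefs, vcov = vc, converged = converged, separated = separated,
    n = nrow(X), design = design, outcome = outcome,
    deviance = fit$deviance,
    null_deviance = fit$null.deviance,
    aic = fit$deviance + 2 * sum(!aliased),
    weighted = !is.null(weights)),
    class = "pooled_logistic")
}

#' Predicted discrete-time hazard from a pooled logistic fit
#'
#' @param fit a `pooled_logistic` object.
#' @param newdata rows at which to predict.
#' @return vector of predicted event probabilities.
#' @export
predict_hazard <- function(fit, newdata) {
  X <- cbind(rep(1, nrow(newdata)), design_matrix(fit$design, newdata))
  co <- fit$coef
  co[is.na(co)] <- 0
  as.numeric(expit(X %*% co))
}

#' @export
print.pooled_logistic <- function(x, ...) {
  cat(sprintf("Pooled logistic fit: outcome '%s', %d person-intervals%s\n",
              x$outcome, x$n, if (x$weighted) " (weighted)" else ""))
  if (!x$converged) cat("  ** fit did not converge **\n")
  if (x$separated) cat("  ** separation suspected **\n")
  print(round(x$coef, 4))
  invisible(x)
}

# Wald/likelihood summaries used by covariate screening
pooled_logistic_pvalue <- function(fit) {
  # likelihood-ratio test of all non-intercept terms vs intercept only
  if (!length(fit$coef) || length(fit$coef) == 1) return(NA_real_)
  null_dev <- fit$null_deviance
  if (is.null(null_dev)) return(NA_real_)
  stats::pchisq(null_dev - fit$deviance, df = length(fit$coef) - 1,
                lower.tail = FALSE)
}
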
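#' Nonparametric subject-level bootstrap
#'
#' Resamples *subjects* (all their person-time rows move together, which is
#' what makes the interval data exchangeable units) with replacement,
#' stratified by randomized arm so arm sizes are preserved, and re-runs the
#' entire estimation procedure — weight fitting plus outcome fitting, or
#' g-formula model fitting plus simulation — on every replicate. Percentile
#' confidence intervals are formed over the successful replicates;
#' replicates on which the procedure errors or returns `NA` are dropped and
#' counted as replicate failures, never retried.
#'
#' @param procedure function taking a resampled `person_time` table and
#'   returning a numeric scalar or named numeric vector.
#' @param table a `person_time` data frame.
#' @param n_samples number of bootstrap replicates (the package defaults
#'   are 1000 for IPCW/ITT-type analyses and 500 for g-formula analyses).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; identical seeds give identical resample indices
#'   and results.
#' @param keep_replicates retain the replicate estimates in the result.
#' @return object of class `bootstrap_result`: `point`, `ci_low`,
#'   `ci_high`, `se` (SD over successful replicates), `level`,
#'   `n_requested`, `n_failures`, `unreliable` (more than half the
#'   replicates failed), `seed`, optionally `replicates`.
#' @export
bootstrap_ci <- function(procedure, table, n_samples = 1000, level = 0.95,
                         seed = 1, keep_replicates = TRUE) {
  stopifnot(n_samples >= 2, level > 0, level < 1)
  check_columns(table, c("subject_id", "arm"), "person-time table")
  point <- procedure(table)
  p <- length(point)

  subj <- unique(table[, c("subject_id", "arm")])
  ids_by_arm <- split(subj$subject_id, subj$arm)
  rows_by_subject <- split(seq_len(nrow(table)), table$subject_id)

  set.seed(seed)
  draws <- lapply(seq_len(n_samples), function(b)
    lapply(ids_by_arm, function(ids)
      sample(ids, length(ids), replace = TRUE)))

  reps <- matrix(NA_real_, nrow = n_samples, ncol = p,
                 dimnames = list(NULL, names(point)))
  failures <- character(0)
  for (b in seq_len(n_samples)) {
    ids <- unlist(draws[[b]], use.names = FALSE)
    idx_list <- rows_by_subject[ids]
    boot_tab <- table[unlist(idx_list, use.names = FALSE), , drop = FALSE]
    # resampled copies of one subject must be distinct subjects
    boot_tab$subject_id <- rep(paste0("b", seq_along(ids)),
                               lengths(idx_list))
    est <- tryCatch(procedure(boot_tab), error = function(e)
      structure(rep(NA_real_, p), failure = conditionMessage(e)))
    if (anyNA(est)) {
      failures <- c(failures, attr(est, "failure") %||% "NA estimate")
    } else {
      reps[b, ] <- est
    }
  }
  ok <- stats::complete.cases(reps)
  alpha <- (1 - level) / 2
  qs <- apply(reps[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(alpha, 1 - alpha), names = FALSE, type = 7)
  out <- list(point = point,
              ci_low = qs[1, ], ci_high = qs[2, ],
              se = apply(reps[ok, , drop = FALSE], 2, stats::sd),
              level = level, n_requested = n_samples,
              n_failures = sum(!ok),
              unreliable = sum(!ok) > n_samples / 2,
              failure_reasons = failures, seed = seed)
  if (keep_replicates) out$replicates <- reps
  class(out) <- "bootstrap_result"
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: %d replicates, %d failure(s)%s\n",
              x$n_requested, x$n_failures,
              if (x$unreliable) "  ** unreliable: >50% failed **" else ""))
  for (i in seq_along(x$point)) {
    nm <- names(x$point)[i] %||% sprintf("est%d", i)
    cat(sprintf("  %s: %s\n", nm,
                fmt_est(x$point[i], x$ci_low[i], x$ci_high[i])))
  }
  invisible(x)
}

#' Write a bootstrap replicate log as CSV
#'
#' One row per replicate: index, estimate(s) or the failure reason.
#'
#' @param result a `bootstrap_result` built with `keep_replicates = TRUE`.
#' @param path file path.
#' @export
write_bootstrap_log <- function(result, path) {
  if (is.null(result$replicates)) {
    stop_ppswitch("bootstrap result was built without keep_replicates")
  }
  df <- as.data.frame(result$replicates)
  names(df) <- names(df) %||% "estimate"
  df <- cbind(replicate = seq_len(nrow(df)), df)
  df$status <- ifelse(stats::complete.cases(result$replicates),
                      "ok", "failure")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
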
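#' @keywords internal
"_PACKAGE"

# inverse logit
expit <- function(x) stats::plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a per-subject RNG seed from a master seed and a subject index so that
# subject i's trajectory is invariant to the total cohort size. Kept below
# 2^31 - 1 (R integer range).
subject_seed <- function(seed, i) {
  m <- 2147483647
  as.integer((((seed %% m) + i * 48271) %% (m - 1)) + 1)
}

stop_ppswitch <- function(...) stop(..., call. = FALSE)

# assert that named columns exist in a data frame
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_ppswitch(sprintf("%s is missing required column(s): %s",
                          what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

# "0.70 (0.42,1.20)" style formatting used throughout reporting
fmt_est <- function(est, lo = NA, hi = NA, digits = 2) {
  f <- function(x) formatC(round(x, digits), format = "f", digits = digits)
  if (is.na(lo) || is.na(hi)) return(f(est))
  sprintf("%s (%s,%s)", f(est), f(lo), f(hi))
}
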
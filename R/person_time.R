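#' Person-time data structures
#'
#' The package works on two related tabular representations of a two-arm
#' trial with one-sided treatment switching:
#'
#' * a *subject table* with one row per subject carrying the randomized arm
#'   (`arm`, 1 = experimental, 0 = control), baseline covariates, and event
#'   months (`progression_month`, `switch_month`, `censor_month`,
#'   `death_month`, each `NA` when absent) plus `max_followup_months`;
#' * a *person-time table* with one row per subject per 30-day interval
#'   (month), indexed from `k = 0`, carrying the current treatment, the
#'   time-varying covariates, and terminal-event indicators.
#'
#' An event recorded "by the end of interval k + 1" is attached to the row
#' with index `k`: a subject dying during interval 3 contributes rows
#' `k = 0..3` with `outcome = (0, 0, 0, 1)`. Death takes precedence over
#' censoring in the same interval; switching is recorded at the start of the
#' interval in which the first experimental dose is taken, so a control
#' subject with `switch_month = 8` has `treatment = 1` from `k = 8` onward.
#'
#' @name person_time
NULL

# baseline covariate columns carried through every person-time row
BASELINE_COLS <- c("age", "ecog", "ics", "race", "sex", "smoking",
                   "strata", "ids", "li", "rt", "tls0")

# structural person-time columns, fixed order for CSV I/O
PT_COLS <- c("subject_id", "k", "arm", "treatment", "dp", "icp",
             "ecog_tv", "tls", "tdp", "outcome", "censored", "switched")

#' Validate a subject table
#'
#' Checks the structural invariants of a subject table: switching only in
#' the control arm and never before progression, death and censoring
#' mutually exclusive, all event months within follow-up.
#'
#' @param subjects subject table (data frame, one row per subject).
#' @return `subjects`, invisibly; stops with an informative error naming the
#'   offending subject otherwise.
#' @export
validate_subjects <- function(subjects) {
  check_columns(subjects,
                c("subject_id", "arm", "progression_month", "switch_month",
                  "censor_month", "death_month", "max_followup_months"),
                "subject table")
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    id <- s$subject_id
    if (!s$arm %in% c(0, 1)) {
      stop_ppswitch(sprintf("subject %s: arm must be 0 or 1", id))
    }
    if (!is.na(s$switch_month)) {
      if (s$arm == 1) {
        stop_ppswitch(sprintf(
          "subject %s: switch_month present in the experimental arm", id))
      }
      if (is.na(s$progression_month) || s$switch_month < s$progression_month) {
        stop_ppswitch(sprintf(
          "subject %s: switching recorded before disease progression", id))
      }
    }
    if (!is.na(s$death_month) && !is.na(s$censor_month)) {
      stop_ppswitch(sprintf(
        "subject %s: death and censoring cannot both be recorded", id))
    }
    months <- c(s$progression_month, s$switch_month, s$censor_month,
                s$death_month)
    if (any(months > s$max_followup_months, na.rm = TRUE)) {
      stop_ppswitch(sprintf(
        "subject %s: event month beyond max_followup_months", id))
    }
  }
  invisible(subjects)
}

#' Expand subject records to a person-time table
#'
#' Emits one row per subject per complete month from `k = 0` up to the
#' month of the terminal event (death or censoring) or the end of follow-up,
#' whichever comes first. Progression status `dp`, time since progression
#' `tdp`, treatment (including control-arm crossover) and the `switched`
#' indicator are derived from the event months. Time-varying `icp`,
#' `ecog_tv` and `tls` are initialised from baseline (the generator writes
#' full monthly trajectories directly; see [generate_trial()]).
#'
#' @param subjects subject table; see [validate_subjects()].
#' @param horizon_months administrative horizon in months (default 48).
#' @return a `person_time` data frame.
#' @export
expand_to_person_time <- function(subjects, horizon_months = 48) {
  stopifnot(horizon_months >= 1)
  validate_subjects(subjects)
  have_baseline <- intersect(BASELINE_COLS, names(subjects))
  pieces <- vector("list", nrow(subjects))
  for (i in seq_len(nrow(subjects))) {
    s <- subjects[i, ]
    end <- min(s$death_month, s$censor_month, s$max_followup_months - 1,
               horizon_months - 1, na.rm = TRUE)
    k <- 0:end
    dp <- if (is.na(s$progression_month)) rep(0L, length(k)) else
      as.integer(k >= s$progression_month)
    switched <- if (is.na(s$switch_month)) rep(0L, length(k)) else
      as.integer(k >= s$switch_month)
    treatment <- if (s$arm == 1) rep(1L, length(k)) else switched
    tdp <- ifelse(dp == 1, k - s$progression_month, 0)
    outcome <- as.integer(!is.na(s$death_month) & k == s$death_month)
    censored <- as.integer(!is.na(s$censor_month) & k == s$censor_month &
                             is.na(s$death_month))
    row <- data.frame(
      subject_id = s$subject_id, k = k, arm = s$arm, treatment = treatment,
      dp = dp, icp = 0L,
      ecog_tv = if ("ecog" %in% have_baseline) s$ecog else 0L,
      tls = if ("tls0" %in% have_baseline) s$tls0 else NA_real_,
      tdp = tdp, outcome = outcome, censored = censored, switched = switched,
      stringsAsFactors = FALSE)
    for (b in have_baseline) row[[b]] <- s[[b]]
    pieces[[i]] <- row
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("person_time", "data.frame")
  out
}

#' Collapse a person-time table back to subject records
#'
#' Inverse of [expand_to_person_time()]: recovers arm, baseline covariates
#' and event months from the row structure.
#'
#' @param table a `person_time` data frame.
#' @return subject table with one row per subject.
#' @export
collapse_person_time <- function(table) {
  check_columns(table, PT_COLS, "person-time table")
  have_baseline <- intersect(BASELINE_COLS, names(table))
  split_tab <- split(table, factor(table$subject_id,
                                   levels = unique(table$subject_id)))
  rows <- lapply(split_tab, function(d) {
    d <- d[order(d$k), ]
    last <- d[nrow(d), ]
    rec <- data.frame(
      subject_id = last$subject_id, arm = last$arm,
      progression_month = if (any(d$dp == 1)) min(d$k[d$dp == 1]) else NA_real_,
      switch_month = if (any(d$switched == 1)) min(d$k[d$switched == 1]) else NA_real_,
      censor_month = if (last$censored == 1) last$k else NA_real_,
      death_month = if (last$outcome == 1) last$k else NA_real_,
      max_followup_months = last$k + 1,
      stringsAsFactors = FALSE)
    for (b in have_baseline) rec[[b]] <- d[[b]][1]
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structural validation of a person-time table
#'
#' Reports (rather than raises) every violation of the person-time row
#' invariants: strictly increasing intervals per subject, absorbing `dp`
#' and `icp`, terminal placement of `outcome` and `censored`, death gated
#' by progression, and control-only switching.
#'
#' @param table a `person_time` data frame.
#' @return data frame with columns `subject_id`, `k`, `rule`; zero rows iff
#'   the table is structurally valid.
#' @export
validate_person_time <- function(table) {
  check_columns(table, PT_COLS, "person-time table")
  stopifnot(nrow(table) > 0)
  bad <- list()
  note <- function(id, k, rule) {
    bad[[length(bad) + 1]] <<- data.frame(subject_id = id, k = k, rule = rule,
                                          stringsAsFactors = FALSE)
  }
  for (d in split(table, factor(table$subject_id,
                                levels = unique(table$subject_id)))) {
    d <- d[order(d$k), ]
    id <- d$subject_id[1]
    if (nrow(d) > 1 && any(diff(d$k) != 1)) {
      note(id, d$k[which(diff(d$k) != 1)[1] + 1], "interval index not step 1")
    }
    for (v in c("dp", "icp")) {
      if (any(diff(d[[v]]) < 0)) {
        note(id, d$k[which(diff(d[[v]]) < 0)[1] + 1],
             sprintf("non-absorbing %s", if (v == "dp") "progression" else v))
      }
    }
    deaths <- which(d$outcome == 1)
    if (length(deaths) > 1) note(id, d$k[deaths[2]], "multiple death rows")
    if (length(deaths) >= 1 && deaths[1] < nrow(d)) {
      note(id, d$k[deaths[1] + 1], "rows after death")
    }
    cens <- which(d$censored == 1)
    if (length(cens) >= 1 && cens[1] < nrow(d)) {
      note(id, d$k[cens[1] + 1], "rows after censoring")
    }
    gated <- which(d$outcome == 1 & d$dp == 0)
    if (length(gated)) note(id, d$k[gated[1]], "death without progression")
    if (d$arm[1] == 1 && any(d$switched == 1)) {
      note(id, d$k[which(d$switched == 1)[1]],
           "switching in experimental arm")
    }
  }
  if (!length(bad)) {
    return(data.frame(subject_id = character(), k = integer(),
                      rule = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, bad)
}

# add one-month lags of the time-varying covariates (plus treatment), used
# by the weighting and g-formula model formulas; lag at k = 0 falls back to
# the baseline state (no prior progression, baseline ECOG/TLS, assigned arm)
add_lagged_covariates <- function(table) {
  ord <- order(table$subject_id, table$k)
  table <- table[ord, ]
  first <- !duplicated(table$subject_id)
  lag1 <- function(x, fill) {
    out <- c(NA, x[-length(x)])
    out[first] <- fill[first]
    out
  }
  table$lag_treatment <- lag1(table$treatment, table$arm)
  table$lag_dp <- lag1(table$dp, rep(0L, nrow(table)))
  table$lag_icp <- lag1(table$icp, rep(0L, nrow(table)))
  table$lag_ecog_tv <- lag1(table$ecog_tv, table$ecog)
  table$lag_tls <- lag1(table$tls, table$tls)
  table
}

#' Read / write person-time tables as CSV
#'
#' The on-disk contract is a headered CSV with the fixed structural columns
#' `subject_id, k, arm, treatment, dp, icp, ecog_tv, tls, tdp, outcome,
#' censored, switched` followed by the baseline covariate columns.
#'
#' @param table a `person_time` data frame.
#' @param path file path.
#' @return `read_person_time()` returns a `person_time` data frame.
#' @export
write_person_time <- function(table, path) {
  cols <- c(PT_COLS, intersect(BASELINE_COLS, names(table)))
  utils::write.csv(table[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_person_time
#' @export
read_person_time <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(out, PT_COLS, "person-time CSV")
  class(out) <- c("person_time", "data.frame")
  out
}

#' Write the person-time data dictionary
#'
#' Companion plain-text dictionary describing every column of the
#' person-time CSV contract.
#'
#' @param path file path.
#' @export
write_data_dictionary <- function(path) {
  dict <- data.frame(
    column = c(PT_COLS, BASELINE_COLS),
    description = c(
      "opaque subject identifier",
      "30-day interval index, integer months from 0",
      "randomized arm (1 = experimental, 0 = control)",
      "treatment actually received during the interval (1 = experimental)",
      "disease progression by interval k (absorbing 0/1)",
      "intracranial disease progression by interval k (absorbing 0/1)",
      "time-varying ECOG performance score (0/1/2)",
      "target lesion size, mm (continuous)",
      "months since progression onset (0 before progression)",
      "death by the end of the interval (terminal row only)",
      "LTFU/administrative censoring by the end of the interval",
      "crossover to experimental treatment occurred by interval k",
      "baseline age, years",
      "baseline ECOG score (0/1/2)",
      "measurable intracranial CNS disease at baseline (0/1)",
      "race (1 = Asian, 0 = non-Asian)",
      "sex (1 = female)",
      "smoking history (1 never / 2 former / 3 current)",
      "randomization strata: brain metastases x prior chemotherapy (1-4)",
      "initial diagnosis stage, 4 categories",
      "lung involvement at study entry, 4 categories",
      "prior radiation therapy (0/1)",
      "baseline target lesion size, mm"),
    stringsAsFactors = FALSE)
  utils::write.csv(dict, path, row.names = FALSE)
  invisible(path)
}
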
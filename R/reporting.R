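#' Configuration-driven analysis runs and publication-style tables
#'
#' A run configuration (YAML file or R list) names the input — a
#' person-time CSV or a generator configuration — the analyses to run, the
#' bootstrap settings and the output directory. [run_analysis_suite()]
#' executes the requested analyses and writes a results bundle: cohort and
#' truth CSVs, a results table `(approach, estimator, measure, estimate,
#' ci_low, ci_high)`, weight diagnostics, and a manifest recording the
#' package version, seed and configuration, so every reported number is
#' traceable to a bundle file.
#'
#' @name reporting
NULL

#' Read a run configuration from YAML
#'
#' Recognized keys: `input` (person-time CSV path) or `generator`
#' (`"feedback"`, `"null"`, or a nested generator configuration),
#' `analyses` (subset of `itt_unadjusted`, `itt_strata`, `itt_baseline`,
#' `itt_marginal`, `pp_exclude_switchers`, `pp_censor_at_switch`,
#' `pp_ipcw`, `gformula`, or `simulate` alone), `horizon`, `seed`,
#' `n_bootstrap` (0 disables CIs), `truncation` (two percentiles), and
#' `simulate_truth` (logical).
#'
#' @param path YAML file path.
#' @return a named list (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "run_config")
}

resolve_run_table <- function(config) {
  if (!is.null(config$input)) return(read_person_time(config$input))
  gen <- config$generator %||% "feedback"
  gcfg <- if (is.character(gen)) {
    switch(gen, feedback = feedback_config(), null = null_config(),
           stop_ppswitch(sprintf("unknown generator '%s'", gen)))
  } else {
    do.call(generator_config, gen)
  }
  gcfg$seed <- config$seed %||% gcfg$seed
  list(config = gcfg, trial = generate_trial(gcfg))
}

default_ipcw_specs <- function() {
  list(
    switch = weight_spec(
      "switching",
      denominator = term_list(k = "linear", tls = "linear",
                              ecog_tv = "linear", tdp = "quadratic"),
      label = "switch-generator-faithful"),
    ltfu = weight_spec(
      "ltfu_ac",
      denominator = term_list(k = "linear"),
      label = "ltfu-time-only"))
}

results_row <- function(approach, estimator, measure, estimate,
                        ci_low = NA_real_, ci_high = NA_real_) {
  data.frame(approach = approach, estimator = estimator, measure = measure,
             estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             stringsAsFactors = FALSE)
}

analysis_rows <- function(an) {
  rbind(
    results_row(an$approach, "pooled_logistic", "dHR", an$effects_pooled$dhr),
    results_row(an$approach, "pooled_logistic", "cHR", an$effects_pooled$chr),
    results_row(an$approach, "pooled_logistic", "RR", an$effects_pooled$rr),
    results_row(an$approach, "km", "cHR", an$effects_km$chr),
    results_row(an$approach, "km", "RR", an$effects_km$rr))
}

#' Execute a configured analysis run
#'
#' @param config a `run_config` (or plain list with the same keys).
#' @param out_dir output directory, created if needed.
#' @return invisibly, the results data frame; files are written to
#'   `out_dir`.
#' @export
run_analysis_suite <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1
  horizon <- config$horizon %||% 48
  analyses <- config$analyses %||% "simulate"

  src <- resolve_run_table(config)
  if (is.data.frame(src)) {
    table <- src; gcfg <- NULL
  } else {
    table <- src$trial$table; gcfg <- src$config
    write_person_time(table, file.path(out_dir, "cohort.csv"))
    utils::write.csv(src$trial$subjects,
                     file.path(out_dir, "subjects.csv"), row.names = FALSE)
    write_data_dictionary(file.path(out_dir, "data_dictionary.csv"))
  }
  if (isTRUE(config$simulate_truth) && !is.null(gcfg)) {
    for (s in c("always_control", "always_experimental")) {
      tr <- simulate_truth(gcfg, s, n_oracle = config$n_oracle %||% 20000,
                           seed = seed + 1)
      write_truth_curve(tr, file.path(out_dir, paste0("truth_", s, ".csv")))
    }
  }

  results <- list()
  n_boot <- config$n_bootstrap %||% 0

  run_one <- function(approach) {
    fn <- switch(approach,
      itt_unadjusted = function(tb) itt_analysis(tb, "unadjusted", horizon),
      itt_strata = function(tb) itt_analysis(tb, "strata", horizon),
      itt_baseline = function(tb) itt_analysis(tb, "baseline", horizon),
      itt_marginal = function(tb) itt_analysis(tb, "marginal", horizon),
      pp_exclude_switchers = function(tb) naive_pp(tb, "exclude",
                                                   horizon = horizon),
      pp_censor_at_switch = function(tb) naive_pp(tb, "censor",
                                                  horizon = horizon),
      pp_ipcw = {
        specs <- default_ipcw_specs()
        function(tb) ipcw_pp_analysis(tb, specs$switch, specs$ltfu,
                                      truncation = config$truncation,
                                      horizon = horizon)
      },
      stop_ppswitch(sprintf("unknown analysis '%s'", approach)))
    an <- fn(table)
    rows <- analysis_rows(an)
    if (n_boot >= 2) {
      bs <- bootstrap_ci(function(tb) {
        a <- fn(tb)
        c(dHR = a$effects_pooled$dhr, cHR = a$effects_pooled$chr,
          RR = a$effects_pooled$rr)
      }, table, n_samples = n_boot, seed = seed + 7)
      for (m in c("dHR", "cHR", "RR")) {
        sel <- rows$estimator == "pooled_logistic" & rows$measure == m
        rows$ci_low[sel] <- bs$ci_low[m]
        rows$ci_high[sel] <- bs$ci_high[m]
      }
      write_bootstrap_log(bs, file.path(out_dir,
                                        paste0("bootstrap_", approach, ".csv")))
    }
    if (!is.null(an$weights)) {
      write_weight_series(an$weights,
                          file.path(out_dir, "ipcw_weights.csv"))
      dg <- an$diagnostics
      utils::write.csv(
        data.frame(mean = dg$mean, sd = dg$sd, min = dg$min, max = dg$max,
                   n = dg$n),
        file.path(out_dir, "ipcw_weight_diagnostics.csv"),
        row.names = FALSE)
    }
    rows
  }

  for (a in setdiff(analyses, c("simulate", "gformula"))) {
    results[[a]] <- run_one(a)
  }
  if ("gformula" %in% analyses) {
    spec <- default_gformula_spec(n_sim = config$n_sim %||% 10000,
                                  horizon = horizon)
    mc <- fit_gformula_models(table, spec, arm = 0)
    me <- fit_gformula_models(table, spec, arm = 1)
    rc <- simulate_counterfactual(mc, "always_control", seed = seed + 11)
    re <- simulate_counterfactual(me, "always_experimental", seed = seed + 12)
    eff <- gformula_effects(rc, re, horizon = horizon)
    results$gformula <- rbind(
      results_row("gformula", "gformula", "risk_control",
                  rc$risk$risk[horizon]),
      results_row("gformula", "gformula", "risk_experimental",
                  re$risk$risk[horizon]),
      results_row("gformula", "gformula", "cHR", eff$chr),
      results_row("gformula", "gformula", "RR", eff$rr))
    utils::write.csv(
      rbind(cbind(strategy = "always_control", rc$risk),
            cbind(strategy = "always_experimental", re$risk)),
      file.path(out_dir, "gformula_risk_curves.csv"), row.names = FALSE)
    nc <- natural_course_check(mc, table,
                               n_sim = config$n_sim %||% 10000,
                               seed = seed + 13)
    utils::write.csv(nc, file.path(out_dir, "natural_course_audit.csv"),
                     row.names = FALSE)
  }

  res <- if (length(results)) do.call(rbind, results) else
    data.frame(approach = character(0), estimator = character(0),
               measure = character(0), estimate = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0),
               stringsAsFactors = FALSE)
  rownames(res) <- NULL
  utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
  manifest <- list(
    package = "ppswitch",
    version = as.character(utils::packageVersion("ppswitch")),
    seed = seed, horizon = horizon,
    analyses = analyses,
    config = unclass(config),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Publication-style summary table
#'
#' One row per (approach, estimator) with dHR / cHR / RR formatted as
#' `"x.xx (x.xx,x.xx)"`.
#'
#' @param results results data frame as written by [run_analysis_suite()].
#' @return data frame of formatted strings (empty with header only when
#'   `results` has no rows).
#' @export
summary_table <- function(results) {
  keys <- unique(results[, c("approach", "estimator")])
  out <- data.frame(approach = character(0), estimator = character(0),
                    dHR = character(0), cHR = character(0),
                    RR = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(keys))) {
    sel <- results$approach == keys$approach[i] &
      results$estimator == keys$estimator[i]
    grab <- function(m) {
      r <- results[sel & results$measure == m, ]
      if (!nrow(r) || is.na(r$estimate[1])) return("")
      fmt_est(r$estimate[1], r$ci_low[1], r$ci_high[1])
    }
    out <- rbind(out, data.frame(
      approach = keys$approach[i], estimator = keys$estimator[i],
      dHR = grab("dHR"), cHR = grab("cHR"), RR = grab("RR"),
      stringsAsFactors = FALSE))
  }
  out
}

#' Weight-specification sensitivity grid
#'
#' Runs the IPCW analysis over a labelled list of switching-weight
#' specifications and tabulates weight diagnostics and effect estimates,
#' one row per specification in input order.
#'
#' @param table a `person_time` data frame.
#' @param specs named list of switching [weight_spec()]s, ordered as the
#'   rows should appear.
#' @param ltfu_spec optional LTFU/AC spec shared across rows.
#' @param horizon effect horizon.
#' @return data frame with columns `specification`, `mean`, `sd`, `min`,
#'   `max`, `cHR`, `RR`.
#' @export
weight_sensitivity_grid <- function(table, specs, ltfu_spec = NULL,
                                    horizon = 48) {
  rows <- lapply(names(specs), function(nm) {
    an <- ipcw_pp_analysis(table, specs[[nm]], ltfu_spec, horizon = horizon)
    dg <- an$diagnostics
    data.frame(specification = nm, mean = dg$mean, sd = dg$sd,
               min = dg$min, max = dg$max,
               cHR = an$effects_pooled$chr, RR = an$effects_pooled$rr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
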
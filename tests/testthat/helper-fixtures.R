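# Shared fixtures, generated in code and memoised across test files.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# small hand-written subject table exercising every event pattern
toy_subjects <- function() {
  data.frame(
    subject_id = c("A", "B", "C", "D", "E"),
    arm = c(1, 0, 0, 0, 1),
    progression_month = c(2, 5, 1, NA, NA),
    switch_month = c(NA, 8, 1, NA, NA),
    censor_month = c(NA, NA, NA, 2, NA),
    death_month = c(3, NA, 6, NA, NA),
    max_followup_months = c(12, 12, 12, 12, 4),
    age = c(60, 55, 48, 71, 63), ecog = c(0, 1, 1, 2, 0),
    ics = c(0, 1, 0, 0, 0), race = c(0, 1, 0, 0, 1),
    sex = c(1, 0, 1, 1, 0), smoking = c(1, 2, 1, 3, 1),
    strata = c(1, 2, 3, 4, 1), ids = c(4, 4, 3, 2, 4),
    li = c(1, 2, 3, 2, 1), rt = c(0, 1, 0, 0, 1),
    tls0 = c(40, 62, 35, 80, 55),
    stringsAsFactors = FALSE)
}

# moderate feedback cohort shared by several files
feedback_trial <- function(n_per_arm = 600, seed = 11) {
  memo(sprintf("fb_%d_%d", n_per_arm, seed), {
    cfg <- feedback_config()
    cfg$n_control <- n_per_arm
    cfg$n_experimental <- n_per_arm
    cfg$seed <- seed
    generate_trial(cfg)
  })
}

null_trial <- function(n_per_arm = 500, seed = 19) {
  memo(sprintf("null_%d_%d", n_per_arm, seed), {
    cfg <- null_config()
    cfg$n_control <- n_per_arm
    cfg$n_experimental <- n_per_arm
    cfg$seed <- seed
    generate_trial(cfg)
  })
}

# the exactly-specified switching weight model: the generator's switching
# hazard is logistic in age (plateaued at 43), TLS, ECOG, time since
# progression and the ECOG x TDP interaction
correct_switch_spec <- function() {
  weight_spec(
    "switching",
    denominator = c(term_list(age_c = "linear", tls = "linear",
                              ecog_tv = "linear", tdp = "linear"),
                    list(term_spec("ecog_tv", "interaction", with = "tdp"))),
    label = "switch-correct")
}

# full prognostic weighting model and the same without time-since-progression
full_switch_spec <- function() {
  weight_spec(
    "switching",
    denominator = term_list(age = "linear", k = "linear", tls = "linear",
                            ecog_tv = "linear", tdp = "quadratic"),
    label = "switch-full")
}

notdp_switch_spec <- function() {
  weight_spec(
    "switching",
    denominator = term_list(age = "linear", k = "linear", tls = "linear",
                            ecog_tv = "linear"),
    label = "switch-no-tdp")
}

ltfu_time_spec <- function() {
  weight_spec("ltfu_ac", denominator = term_list(k = "linear"),
              label = "ltfu-time")
}

# add the derived age-plateau column used by the exactly-specified models
with_age_plateau <- function(table) {
  table$age_c <- pmax(table$age, 43)
  table
}

oracle_truth <- function(strategy, n_oracle = 20000, seed = 101) {
  memo(sprintf("truth_%s_%d_%d", strategy, n_oracle, seed),
       simulate_truth(feedback_config(), strategy, n_oracle = n_oracle,
                      seed = seed))
}
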
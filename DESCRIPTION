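Package: ppswitch
Title: Per-Protocol Survival Effects Under Treatment Switching via IPCW
    and the Parametric G-Formula
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates per-protocol effects of sustained treatment
    strategies on overall survival in two-arm randomized trials with
    one-sided treatment switching. Implements discrete-time survival
    analysis on 30-day person-time tables, inverse probability of
    censoring weighting (IPCW) for treatment switching and loss to
    follow-up with stabilization, truncation and diagnostics, the
    noniterative-conditional-expectation parametric g-formula with
    deterministic restrictions and natural-course diagnostics, an
    intention-to-treat and naive per-protocol analysis battery, and
    subject-level bootstrap confidence intervals with replicate-failure
    accounting. A synthetic two-arm trial generator with
    treatment-confounder feedback provides ground-truth counterfactual
    risks for validating the estimators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
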
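Package: bnmdyn
Title: Dynamic Analysis of Delayed-Coupling Brain Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates whole-brain resting-state activity with two delayed-coupling
    neural-mass models (Kuramoto phase oscillators and a linear firing-rate model)
    on a structural connectome, converts neural activity to BOLD with the
    Balloon-Windkessel hemodynamic model, and characterizes the resulting signals
    with the dynamic analysis methods used for resting-state fMRI: average
    functional connectivity and spectral slope, point-process coactivation,
    quasiperiodic-pattern discovery, sliding-window k-means state analysis, and
    recurrence quantification analysis. Includes a synthetic connectome generator
    and a surrogate resting-state generator so the full simulate-and-compare study
    runs without external imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
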
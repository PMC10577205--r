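Package: burnoutERP
Title: Go/NoGo ERP Simulation, N2-P3 Peak Extraction, and Burnout Biomarker Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Executive reaction-time (Go/NoGo) test sessions and
    multichannel EEG epochs with embedded N2 and P3 event-related potential
    components, implements the matching preprocessing and measurement chain
    (linked-mastoid re-reference, zero-phase band-pass filtering, peak-to-peak
    artifact rejection, condition averaging, windowed peak detection, channel
    pooling, N2-P3 interpeak latency), and reproduces the statistical layer of
    an occupational-burnout ERP biomarker study: Kruskal-Wallis group
    contrasts, mixed-effects logistic error models, Spearman correlations, and
    linear biomarker regressions of questionnaire scores on centroparietal P3
    amplitude and N2-P3 interpeak latency. Includes readers and writers for
    BrainVision Core format files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    lme4,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
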
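Package: pwdop
Title: Virtual Dual-Transducer Pulsed-Wave Carotid Doppler for Hemodynamic Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A software "virtual device" for hands-free dual-transducer pulsed-wave
    carotid Doppler monitoring, together with a physiologically calibrated scenario
    simulator. Generates ground-truth hemodynamic scenarios (controlled hypotension
    by vena cava occlusion, ventricular fibrillation with defibrillation and return
    of spontaneous circulation, true pulseless electrical activity), synthesizes
    dual-transducer multigate complex-baseband Doppler signals from them, and
    implements the full measurement chain: wall filtering, spectrogram and colour
    M-mode computation, automatic gate selection, maximum-velocity envelope tracing,
    beat detection, per-beat hemodynamic indices (PSV, EDV, TAV, RI, PI, HR),
    dual-transducer angle correction, and flow-state classification. A statistics
    stage fits hierarchical linear mixed models of time-averaged velocity on mean
    arterial pressure with nested animal/sequence random effects and reports
    variance-component intraclass correlation coefficients with bootstrap intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    generics,
    lme4,
    signal,
    jsonlite,
    yaml,
    data.table,
    withr,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
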
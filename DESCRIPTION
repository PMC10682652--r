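Package: vploop
Title: Velocity-Pressure Loop Analysis of Aortic Stenosis Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds velocity-pressure (VP) loops from paired ascending-aorta
    pressure and left-ventricular-outflow-tract Doppler velocity recordings,
    extracts the loop landmarks and angles (ALPHA, BETA, GALA) together with
    the afterload index [P(Vmax) - P(Vo)]/Vmax, and evaluates the index as a
    predictor of objective functional improvement after transcatheter aortic
    valve implantation (TAVI).  Includes ECG-gated beat segmentation and
    ensemble averaging, conventional hemodynamic comparators (valvuloarterial
    impedance, arterial distensibility), the objective/subjective improvement
    endpoint rules, class-imbalanced logistic modelling with smoothed-bootstrap
    oversampling and bagged ensembles, ROC analysis with DeLong confidence
    intervals, Kaplan-Meier/log-rank survival comparison, and a synthetic
    waveform and cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
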
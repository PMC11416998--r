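Package: evpcea
Title: Cost-Effectiveness of First-Line Enfortumab Vedotin plus
    Pembrolizumab in Metastatic Urothelial Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A partitioned-survival cost-effectiveness pipeline for first-line
    enfortumab vedotin plus pembrolizumab versus platinum-based chemotherapy
    in metastatic urothelial carcinoma, from the US payer perspective.
    Includes a synthetic two-arm trial emulator, pseudo individual-patient
    data reconstruction from digitized Kaplan-Meier curves and number-at-risk
    tables (Guyot-style inversion), parametric survival fitting with AIC
    model selection (including Royston-Parmar splines and a mixture-cure
    model), a three-state (progression-free / progressed / dead) cohort
    engine with half-cycle correction, discounting, background-mortality
    floor and oncology dosing rules, and one-way, two-way, probabilistic,
    price-threshold and subgroup sensitivity analyses with
    cost-effectiveness acceptability curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    flexsurv,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
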
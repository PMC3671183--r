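Package: episcan
Title: Depth-Profile Quantification of In Situ Hybridization Signal in
    Layered Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies RNA in situ hybridization (RISH) signal along the
    depth axis of layered sensory epithelia such as the mouse olfactory
    epithelium. Extracts line-intensity scans perpendicular to a traced
    basal lamina, normalizes and averages them hierarchically (scans within
    animal, then across animals) on fixed interpolation grids with per-point
    SEM, computes trapezoidal area integrals of averaged profiles over
    marker-defined depth windows, and compares probe distributions within a
    window by the two-sample Kolmogorov-Smirnov statistic. A companion qPCR
    stage computes relative expression by the 2^-dCt and 2^-ddCt methods and
    tests gene differences by one-way ANOVA with Tukey's post-hoc procedure.
    Includes a seeded synthetic-data generator (layered epithelium images
    with a curved basal lamina, and Ct tables with designed fold changes)
    providing ground truth for every stage, and a config-driven pipeline
    runner producing machine-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    tiff,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
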
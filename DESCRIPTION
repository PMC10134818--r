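Package: mepscope
Title: Quantitative Metabolomics of MEP-Pathway Bottlenecks in Zymomonas mobilis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for isotope-ratio absolute metabolite quantification,
    time-course and single-time-point differential metabolomics with
    Benjamini-Hochberg FDR control, metabolite-pool accounting, in vivo
    pathway thermodynamics (deltaG = deltaG0' + RT lnQ), growth and
    isoprene-yield physiology, and reaction-level bottleneck scoring for the
    methylerythritol 4-phosphate (MEP) isoprenoid pathway of Zymomonas
    mobilis. Includes a synthetic LC-MS data generator with known ground
    truth so every stage of the pipeline can be exercised and validated
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
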
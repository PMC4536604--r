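Package: cd4iqc
Title: Internal Quality Control Analytics for CD4 Count Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two internal quality control (IQC) schemes used in
    CD4 T-cell enumeration laboratories: duplicate analysis, in which a
    previous-day patient sample is re-tested and judged by the percent
    variation between the two counts, and commercial stabilized controls,
    monitored on Levey-Jennings charts under Westgard multirules against
    manufacturer or laboratory-established ranges.  Provides the full
    statistical kernel (percent variation, mean absolute percent variation,
    coefficient of variation, regression r-squared, Bland-Altman limits of
    agreement, QC failure rates per laboratory-year, cross-laboratory daily
    mean and standard error trends), range establishment from 10 or 20 runs,
    monthly precision summaries, chart-data exports, a seeded synthetic
    multi-laboratory QC data generator with injectable shift, drift and
    outlier events, and a command-line interface over CSV logs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
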
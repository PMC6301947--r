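Package: saltmig
Title: Quantitative Analysis of Saltatory Tumor Cell Migration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies heterogeneous, saltatory ("pause and burst") cell
    migration from time-lapse centroid tracks. Computes per-cell kinematic
    metrics (instantaneous speed, path lengths, directionality, effective
    speed, speed variability), detects movement peaks (bursts) and
    high-speed peaks, quantifies distance traveled per movement, assembles
    population speed topographies, and compares control versus drug-treated
    populations with t-tests, Spearman correlations and Levene's
    variance-equality test. Includes a two-state pause/burst random-walk
    simulator of tumor-cell migration with a fast subpopulation and a
    selective drug effect, providing ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    jsonlite,
    minpack.lm,
    stats,
    tibble,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
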
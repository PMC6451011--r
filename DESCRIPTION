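Package: actisleep
Title: Accelerometer-Derived Sleep Phenotypes, GWAS Post-Processing and
    Mendelian Randomisation
Version: 0.1.0
Authors@R:
    person("Sleep", "Genetics Tools", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives sleep phenotypes from wrist-worn tri-axial
    accelerometer recordings using a diary-free heuristic: the z-angle of
    the device is tracked across 5-second epochs, a rolling-median
    change metric separates movement from non-movement, and the longest
    merged block of nocturnal inactivity defines the sleep period time
    window (SPT-window).  Within that window, sleep episodes are scored
    as sustained periods with no posture change larger than 5 degrees.
    Eight phenotypes (sleep duration and its night-to-night variability,
    sleep efficiency, number of nocturnal sleep episodes, sleep
    midpoint, L5 and M10 timing, diurnal inactivity) are aggregated per
    individual with a quality-control exclusion cascade.  The package
    also ships a calibrated synthetic-cohort generator with ground
    truth, utilities for GWAS summary-statistic post-processing
    (threshold accounting, allele alignment, variance explained,
    binomial sign tests, inverse-variance meta-analysis, genomic
    inflation), and two-sample Mendelian-randomisation estimators (IVW,
    MR-Egger, weighted and penalised weighted median) with iterative
    Cochran's-Q instrument pruning.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
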
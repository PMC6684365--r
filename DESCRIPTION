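Package: shsexposure
Title: Second-Hand Smoke Occupational Exposure Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing workplace exposure to second-hand tobacco
    smoke (SHS) from multi-method monitoring campaigns: conversion of
    two-channel optical particle counts (Dylos DC1700) to PM2.5 mass
    concentrations with per-device calibration, area and mobile exposure
    summaries with threshold-exceedance statistics, passive-sampler airborne
    nicotine processing with limit-of-detection imputation and QC exclusion
    rules, and a salivary-cotinine toxicokinetic back-calculation that
    converts pre/post-shift biomarker increments into shift-average SHS-PM2.5
    equivalents via published dosimetry ('Rosetta Stone') relations. Includes
    a synthetic-data generator emulating diurnal smoking-driven indoor PM so
    the full pipeline can be exercised without access to the original
    measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
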
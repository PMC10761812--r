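Package: pdhbm
Title: Home-Based Monitoring Analytics for Parkinson's Motor Fluctuations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for smartwatch home-based monitoring of
    advanced Parkinson's disease. Consumes free-living symptom streams
    (binary tremor and dyskinesia detections per 30-s window, activity
    level per 5-s window), medication intake logs, 30-min symptom diaries
    and daily motor-task records; computes protocol-compliance measures,
    daily and overall symptom prevalence, diary-aligned ON/OFF statistics,
    motor-task ON/OFF comparisons and medication-cycle phase-normalized
    fluctuation signatures; classifies patients into four motor-fluctuation
    profiles (dose-responsive, time-of-day, constant, irregular) and draws
    longitudinal raster plots. Includes a synthetic cohort generator for
    the four fluctuation archetypes so the whole pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
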
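Package: nocirig
Title: Virtual Rig for Automated Nocifensive Withdrawal Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hardware-free computational core of an automated
    nocifensive-behavior testing rig for mice. Implements
    millisecond-precision paw-withdrawal detection from photodetector
    reflectance, paw-height and indenter-force signals (offline and
    streaming, for closed-loop stimulus termination), proportional
    automated aiming on pose-estimation key points, interleaved
    multi-animal session scheduling, and the accompanying analyses:
    signal-to-noise and coefficient-of-variation summaries of stimulus
    delivery, Bland-Altman method agreement, fast/slow latency
    classification with chi-square tests, power-law stimulus-response
    fits, psychometric threshold estimation, latency-distribution
    comparisons, and behavior-latency association with bootstrap
    confidence intervals. A built-in virtual rig (beam geometry,
    tester-jitter models, virtual paw kinematics, key-point streams)
    generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
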
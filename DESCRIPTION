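Package: panhar
Title: Body-Worn Sensor Network Ensembles for Human Activity Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for human activity recognition with a personal area network
    of body-worn inertial sensor nodes (waist, chest, leg, arm). Each node
    classifies its own accelerometer/gyroscope windows locally; a main node
    aggregates the reported results with a weighted vote; supporting nodes
    transmit only for activity classes in a per-node transmit set, found by a
    greedy accuracy-tolerant minimization. Includes a synthetic multi-position
    IMU signal generator, a raw-signal preprocessing pipeline (trimming,
    decimation, gravity separation, sliding windows), two classifier backends
    (a feature-based multinomial model and a native LSTM), a time-stepped
    network simulator with node-failure injection, and reporting helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    nnet,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
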
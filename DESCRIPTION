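Package: pocketgait
Title: Gait Speed from a Pocket-Worn Smartphone IMU via an Inverted
    Pendulum Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates spatiotemporal gait parameters (stride time, step
    length, gait speed) from a single smartphone inertial measurement unit
    carried in a pants pocket. Raw tri-axial accelerometer and gyroscope
    streams are rotated into a gravity-aligned global frame, heel strikes
    are detected from the vertical acceleration, and step length is
    derived from the vertical excursion of the device through an inverted
    pendulum model with a zone-coefficient multiplicative bias correction.
    Includes the calibration procedure that derives zone coefficients
    against a reference system, the agreement and reliability statistics
    used to validate such devices (Passing-Bablok orthogonal regression,
    Bland-Altman limits of agreement, one-way random-effects intraclass
    correlation), and a ground-truth-annotated synthetic walking-signal
    generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    pracma,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
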
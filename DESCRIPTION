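Package: headgest
Title: Head-Gesture Recognition from IMU Time Series by Activity
    Detection and Dynamic Time Warping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Recognizes six head gestures (nod, tilt up, shake left/right,
    tilt left/right) from six-channel inertial measurement unit recordings
    (triaxial acceleration and angular velocity at a fixed sampling rate).
    Segments a continuous stream with an angular-velocity-magnitude
    endpoint detector with duration gating, builds one reference template
    per gesture class by element-wise averaging of variable-length
    training segments truncated to their median length, and classifies
    extracted segments by minimum dynamic-time-warping distance to the six
    templates. Includes arctangent amplitude normalization, sliding median
    filtering for impulse noise, a seeded synthetic gesture and stream
    generator for end-to-end testing, detector parameter sweeps, and a
    train/test evaluation harness with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
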
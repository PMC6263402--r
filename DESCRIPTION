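Package: stepscan
Title: Template-Based Step Detection for Foot-Worn Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects individual steps (start and end times) in
    three-component foot-worn inertial measurement unit recordings by
    sliding a library of step templates along the signal with the Pearson
    correlation coefficient, greedily placing non-overlapping candidate
    steps above a correlation threshold, and discarding low-amplitude
    matches.  Includes an adapted Pan-Tompkins peak detector as a
    comparison baseline, event-level precision/recall evaluation with
    signed start/end/duration errors, and a synthetic gait simulator that
    produces ground-truthed recordings for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
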
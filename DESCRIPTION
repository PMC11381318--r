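Package: tanlab
Title: Pause-Response Analysis of Striatal Tonically Active Neurons in Timing Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the activity of striatal tonically active
    neurons (TANs, putative cholinergic interneurons) recorded while subjects
    perform self-timed movement or Pavlovian timing tasks. Provides a plain-text
    session format for trial events and spike trains, a synthetic session
    generator with scalar-timing behavior and gamma-renewal spike trains with
    injectable event-locked pauses and rebounds, sliding-window nonparametric
    detection of pause responses against a pre-cue control period, fixed-window
    response-magnitude quantification in percent change from baseline, and the
    group-level statistics linking TAN responses to interval duration, movement
    timing, consecutive-correct-trial history and striatal region (chi-square
    proportion tests, rank tests with tie and continuity correction, trend and
    binning analyses, population curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
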
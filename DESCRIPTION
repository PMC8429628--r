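Package: autobilayer
Title: Simulation and Analysis of Automated Artificial-Bilayer Single-Channel Recordings
Version: 0.1.0
Authors@R: person("Autobilayer", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating and analysing automated artificial lipid
    bilayer single-channel electrophysiology experiments. Provides a two-state
    Markov gating simulator with zero-truncated Poisson channel incorporation,
    a rule-based channel-current detector (amplitude/onset/return-time rule on
    1 kHz streams), a probe-descent feedback acquisition controller state
    machine, single-channel idealization and unitary-amplitude estimation,
    current-voltage slope-conductance fitting, blocker-effect condition
    comparison via Welch's t-test, capacitance-based membrane area estimation,
    and Axon Text Format (ATF) trace input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
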
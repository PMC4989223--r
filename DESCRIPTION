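Package: acellsim
Title: Electrical Activity of Human Pancreatic Alpha-Cells with Electrogenic SGLT2 Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hodgkin-Huxley conductance-based simulator of human pancreatic
    alpha-cell (A-cell) electrical activity coupled to a six-state kinetic model
    of the electrogenic Na+/glucose co-transporter SGLT2. Runs glucose-step and
    SGLT2-inhibition (dapagliflozin) protocols, voltage-clamp decomposition of
    the SGLT2 current into transient and sustained components, action-potential
    feature extraction, background (resting) conductance measurements, and
    steady-state glucose flux-balance analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
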
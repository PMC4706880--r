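Package: hcmsim
Title: Discrete-Time Simulator of Hippocampal Change Management of Cortical Receptive Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A discrete-time circuit simulator of the hippocampal system acting as a
    change manager for cortical receptive fields. Cortical columns built from
    two-compartment pyramidal units (basal = direct sensory field, apical = indirect
    field) expand their receptive fields only when and where a dentate gyrus / CA3
    competition converts stimulus novelty into self-limiting expansion-target
    selection, relayed through a perirhinal P1/P2/P3 deep-neuron microcircuit that
    also records and retrieves multi-moment episodic traces via delayed-firing
    neurons. Includes a synthetic stimulus world with controllable novelty, an
    experiment harness that turns the circuit's falsifiable activity predictions
    into automated assertions, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
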
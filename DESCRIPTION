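Package: isfetsim
Title: Analytical Simulation of 2D-Material ISFET Biosensors with LC
    Frequency Readout
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lumped-element simulator for ion-sensitive field-effect
    transistor (ISFET) biosensors built on two-dimensional Dirac channels
    (silicene, graphene).  Implements the quantum-capacitance model of the
    channel, the four-capacitor equivalent circuit of the
    electrolyte-oxide-semiconductor stack, square-law drain-current and
    threshold-voltage electronics, and an inductor-capacitor (LC) resonant
    frequency readout.  A DNA hybridization front end scores probe/target
    sequence pairs, maps hybridization extent to proton release, pH change
    and channel carrier-density shift, and propagates the shift through the
    capacitance chain to a resonant-frequency shift.  Includes parameter
    sweep drivers, a YAML configuration layer, seeded synthetic FASTA
    fixture generation, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
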
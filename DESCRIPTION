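Package: migtol
Title: Agent-Based Dynamics of Migrant Influx and Resident Tolerance
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-time agent-based simulation of migrant entry into a
    city of tolerance-bearing residents, in the tradition of the Schelling
    segregation model. Migrants attempt entry into randomly chosen
    neighbourhoods with a probability that decays exponentially in the
    resident share of the target neighbourhood; all agents relocate when the
    fraction of opposite-type agents in their neighbourhood exceeds their
    tolerance. The package provides the simulation engine, tolerance-breach
    and segregation observables (current and ever-breached resident
    fractions, mean time to first breach, cell segregation indicator), a
    seeded ensemble runner with scenario registry and CSV/JSON reporting,
    and a closed-form deterministic counterpart of the breach cascade
    together with a discrete-event oracle for validating it.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
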
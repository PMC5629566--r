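Package: pessknock
Title: Pessimistic Bi-Level Optimization for Robust Metabolic Strain Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constraint-based design of reaction-knockout strains for targeted
    biochemical overproduction on stoichiometric metabolic models. Implements
    the optimistic bi-level baselines OptKnock and the LP variant of ROOM
    (regulatory on/off minimization) as single-level mixed-integer programs via
    strong duality, together with their pessimistic counterparts P-OptKnock and
    P-ROOM, which maximize the worst-case target flux over an
    epsilon-approximation band of near-optimal cellular responses. Also
    provides flux balance analysis, a worst-case evaluator for fixed knockout
    designs, an exhaustive enumeration oracle, epsilon/K sweep experiments,
    self-contained toy fixtures, and readers for SBML (Level 3 FBC) and a JSON
    tabular model dialect. Mixed-integer programs are solved with the HiGHS
    solver through SciPy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: Python (>= 3.9) with numpy and scipy (>= 1.9) on the PATH
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
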
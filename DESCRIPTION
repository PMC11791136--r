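Package: calredox
Title: Calcium-Coupled Redox Analysis of Multiheme Cytochromes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of spectroelectrochemical titrations of multiheme
    c-type cytochromes whose redox potentials are modulated by bound
    calcium ions.  Provides constrained multi-transition Nernst fitting
    of optically monitored redox titrations (including a paired
    four-transition model for partially calcium-loaded protein), a
    four-state thermodynamic square linking heme oxidation state to
    calcium occupancy, competitive calcium-binding equilibrium solvers
    for indicator-dye based dissociation-constant estimation, a survey
    tool for heme-iron to calcium distances in macromolecular structures,
    and forward-model simulators that generate every input the analysis
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
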
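Package: nucdyn
Title: Comparative Analysis of Nucleosome Molecular Dynamics Trajectories
Version: 0.9.0
Authors@R:
    person("Core", "Maintainers", email = "maintainers@nucdyn.example.org",
           role = c("aut", "cre"))
Description: Tools to contrast the structural dynamics of two nucleosome (or
    general biomolecular) systems from molecular dynamics trajectories:
    Kabsch superposition and trajectory alignment, per-residue and
    per-basepair root-mean-square fluctuations with a trajectory-thirds
    significance procedure, center-of-mass distance series between histone
    dimers, fractional residue contact maps and salt-bridge tracking,
    C-alpha principal component analysis with free-energy-landscape basin
    and barrier quantification, and event-coincidence analysis of DNA
    detachment episodes.  A synthetic-trajectory generator with planted
    ground truth (Gaussian site noise, low-rank collective modes, two-state
    switching, scripted DNA detachment) makes every stage testable without
    molecular dynamics runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
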
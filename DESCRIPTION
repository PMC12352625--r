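Package: hemelink
Title: Haem-Site Geometry, Crosslink Classification and Spectral-Shift
    Analysis for Cytochrome P460 Models
Version: 0.1.0
Authors@R:
    person("hemelink", "developers", email = "hemelink@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for discriminating single- from
    double-crosslinked P460 haem models. Reads protein coordinate files
    (PDB, mmCIF, XYZ), resolves alternate conformations, and computes
    haem-c site descriptors (Fe out-of-plane displacement, coordination
    distances, macrocycle planarity) with rule-based classification of
    the lysine-porphyrin crosslink state and of exocyclic bond character.
    Convolves excitation stick spectra with Gaussian line shapes, assigns
    Soret maxima and computes ferric/ferrous spectral shifts. Derives
    water-residence, distance-distribution and hydrogen-bond occupancy
    statistics from multi-frame trajectories, including bimodality
    detection. Fits atomic partial charges to electrostatic-potential
    grids under hard total-charge, group-neutrality and equivalence
    constraints. A seeded synthetic-data generator produces idealized
    porphyrin sites, trajectories, stick spectra and charge-fitting
    problems with machine-checkable ground truth so every stage is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
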
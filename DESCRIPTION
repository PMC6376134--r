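Package: abforce
Title: Antigen-Antibody Interface Contacts and Coarse-Grained Unbinding Forces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale characterisation of antibody recognition of protein
    antigens such as myelin oligodendrocyte glycoprotein (MOG). Provides a
    PDB-backed structural data model with residue chemistry tables, geometric
    detection of interface hydrogen bonds (donor-acceptor distance and H-D-A
    angle criteria) and salt bridges, anchor-residue ranking and CDR
    attribution, Kabsch superposition and RMSD time series, gas-phase
    molecular-mechanics interface energy decomposition, a coarse-grained
    constant-velocity steered-pulling simulator with rupture-force replicate
    statistics, AFM retract-curve adhesion extraction, and comparison of
    simulated unbinding forces with force-spectroscopy adhesion events.
    Includes generators for synthetic antigen-antibody complexes with planted
    interface contacts, noisy trajectories, and AFM-style retract curves, so
    the whole pipeline is testable without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
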
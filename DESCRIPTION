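Package: nifscreen
Title: In Silico Compatibility Screening of Electron Carriers with the
    Nitrogenase Fe Protein
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens docked complexes of protein electron carriers
    (ferredoxins and flavodoxins) against the nitrogenase Fe protein for
    electron-transfer compatibility.  Parses PDB-format docking models,
    detects iron-sulfur cluster and flavin cofactors, measures
    edge-to-edge inter-cofactor distances, enumerates interface salt
    bridges including conserved Fe-protein hotspot residues, evaluates
    empirical electron-tunneling rates over redox-potential and distance
    grids (Moser-Dutton ruler with exergonic and endergonic branches),
    classifies carriers against distance and rate thresholds, and
    regresses cofactor distance against nitrogenase activity.  Includes a
    deterministic synthetic-complex generator that builds two-body
    pseudo-complexes with exact requested cofactor distances and planted
    salt bridges, plus cohort generators with planted group structure,
    so the full pipeline is testable without external structures.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
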
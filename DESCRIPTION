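Package: nbblueprint
Title: Nanobody HCDR3 Blueprint Classification and Disulphide Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying the global HCDR3 conformation ("blueprint")
    of camelid single-domain antibodies (VHH / nanobody) as kinked or extended,
    from structure or from sequence. Computes the six structural descriptors of
    the blueprint (stem pseudo-torsion and pseudo-bond angles, HCDR3-FR2
    contact density, and FR2 key-position relative solvent accessibility via a
    built-in Shrake-Rupley solvent-accessible surface area routine), applies a
    parameterized logistic structure classifier, mines framework hallmark
    residues by log2 fold-change enrichment with Fisher's exact test, trains a
    soft-label logistic sequence classifier, scores disulphide-bridge geometry
    (SG-SG and CB-CB distance bands, S-S-CB angle, chi3 dihedral, distogram
    cross-entropy) with a cysteine-pairing procedure, and evaluates predicted
    structures against references (framework superposition, region-stratified
    backbone RMSD with bootstrap confidence intervals, blueprint and
    non-canonical-disulphide recovery). Includes seeded synthetic fixture
    generators so the whole surface is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
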
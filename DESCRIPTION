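Package: pocketrank
Title: Binding-Pocket Detection, Druggability Scoring and Target Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grid-based detection of cavities on protein structures read from
    PDB files, computation of the pocket descriptors that druggability scores
    consume (volume, buriedness via solvent-accessible surface area,
    hydrophobicity, site points, enclosure, hydrophilic/hydrophobic character),
    drug-like-density (DLID) and SiteMap-style SiteScore/Dscore scoring,
    min-max fusion of per-method target scores into a composite ranking, and
    post-processing of docking score tables (threshold filtering, best-hit
    selection, cross-target inhibitor overlap). Includes seeded generators for
    synthetic cavity structures and score/docking tables, plus packaged
    machine-readable copies of the study tables used as verification fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
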
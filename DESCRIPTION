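Package: sapofold
Title: Structural Analysis of Disulfide-Stabilized Saposin-Fold Surfactant Peptides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrative structural analysis of disulfide-stabilized helix-hairpin
    (saposin-fold) peptides such as the lung surfactant protein B construct
    Super Mini-B. Reads multi-model PDB coordinate sets and computes disulfide
    chi dihedrals, S-S distances and Katz-Kossiakoff dihedral strain energies
    with conformer-ensemble statistics; fits local and global helix axes from
    sliding four-CA windows (HELANAL-style) and inter-helix axis angles;
    validates models with Procheck-convention Ramachandran classification and
    Kabsch least-squares backbone superposition RMSD over mapped segments;
    maps disulfide connectivity from pepsin-digest monoisotopic masses by
    enumerating cysteine pairings and scoring crosslinked-fragment masses; and
    quantifies CD mean residue ellipticity and 13C isotope-edited FTIR amide I
    band shifts. Includes seeded generators for every synthetic input the
    analyses need (ideal helices, hairpins at set axis angles, disulfide
    fixtures realizing specified dihedrals, Gaussian band spectra, digest mass
    observations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    seqinr
Config/testthat/edition: 3
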
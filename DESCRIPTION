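Package: sbsmma
Title: Structure-Based Statistical Mechanical Model of Allostery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Per-residue allosteric free energy and allosteric modulation
    from coarse-grained elastic network models of protein structures.
    Ligand binding and stabilizing (UP) or destabilizing (DOWN) point
    mutations are modelled as perturbations of the C-alpha contact
    network; the free energy of the allosteric response is obtained from
    the normal-mode ensembles of the unperturbed and perturbed networks.
    Exhaustive single-position mutation scans yield Allosteric Signaling
    Maps, complemented by inter-residue distance matrices, site-to-site
    signaling tables, and export to CSV, JSON and B-factor-annotated PDB.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
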
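Package: memtether
Title: Membrane-Contact and Positioning Analysis for Tethered GTPase Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular trajectories of membrane-tethered
    proteins, built around the observables used to compare Rho-family GTPases
    (such as RND1 and RhoD) bound to plexin at the inner membrane leaflet:
    Shrake-Rupley solvent-accessible surface areas and SASA-difference contact
    areas, alignment-frame RMSD observables via Kabsch superposition,
    per-residue lipid-contact profiles and contact maps with a 5 Angstrom
    molecule-level criterion, anionic-lipid enrichment at the protein-membrane
    interface, and a sequence census of charged residues at the putative
    membrane interface of Rho-family GTPases together with C-terminal tail
    lengths. A coarse-grained Metropolis Monte Carlo generator of a
    membrane-tethered bead domain with a tunable charged surface patch and
    tail length provides synthetic trajectories in the package's own input
    formats, standing in for microsecond molecular dynamics.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
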
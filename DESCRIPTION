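Package: ldbind
Title: Protein Binding Analysis for Lipid-Droplet Monolayers and Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for protein-membrane association in molecular
    models of lipid-droplet (LD) surfaces. Quantifies per-residue
    protein-membrane contacts with a sigmoid distance-weighted contact
    function, residue penetration-depth probability maps relative to the
    membrane center, and lipid packing defects on monolayer leaflets via a
    grid classifier with exponential defect-size fitting. Includes
    amphipathic-helix analytics (helical-wheel projection, Wimley-White
    interfacial hydrophobicity sums, hydrophobic moment, backbone dihedrals
    and helicity calls), membrane composition tables with exact lipid-count
    allocation, and a deterministic synthetic-trajectory generator that
    emulates bilayer and core-filled monolayer patches with scripted
    protein binding and stochastic neutral-lipid surfacing events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
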
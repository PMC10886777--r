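Package: pocketfp
Title: Protein-Ligand Interaction Fingerprints and Reactivity Descriptors
    from Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Geometric interaction fingerprinting of protein-ligand
    complexes over molecular-dynamics trajectories: per-frame detection of
    hydrogen bonds, water bridges, salt bridges, hydrophobic contacts and
    pi-pi / pi-cation stacking under configurable distance and angle
    criteria; per-residue contact-frequency tables and persistence
    timelines; superposition-based RMSD and RMSF statistics; hierarchical
    clustering of ligand poses with representative (medoid) frame
    selection; and conceptual-DFT global reactivity descriptors
    (ionization potential, electron affinity, hardness, softness,
    electronegativity, electrophilicity) of small-molecule ligands from
    species energies or frontier-orbital energies.  Includes a seeded
    synthetic binding-pocket trajectory generator with planted
    probabilistic interactions for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
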
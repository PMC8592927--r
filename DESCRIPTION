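Package: poreGating
Title: Pore Geometry, Side-Chain Rotation and Gating-State Analysis of
    Hexameric Channel Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing toolkit for molecular dynamics trajectories of
    homo-hexameric ion channels such as Orai/CRAC. Computes HOLE-style pore
    radius profiles by deterministic multi-start probe maximisation, gate
    radii and closed/dilated state classification, per-subunit side-chain
    rotation and orientation angle statistics with Boltzmann-inversion free
    energies, water and ion occupancy in residue-bounded axial cylinders,
    3D density grids with OpenDX export, ring radii, Kabsch-superposed
    RMSD series and average structures, and inter-residue contact
    distances. Includes a synthetic channel-trajectory generator with
    exact programmable ground truth (gate clearance, rotation angles,
    hydration and ion counts) so that every statistic is verifiable at
    desk scale without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    bio3d,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
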
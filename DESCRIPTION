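Package: trajmaps
Title: Trajectory Maps: Per-Residue Shift Heatmaps for Molecular Dynamics Trajectories
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders protein molecular dynamics trajectories as residue-by-frame
    heatmaps ("trajectory maps") of backbone center-of-mass displacements from a
    reference frame. Supports replicate averaging and difference maps with a
    divergent colour scale, region shift-graphs with moving-average smoothing,
    Calpha RMSD overlays, a CSV interchange format for shift matrices, readers
    for common pre-aligned trajectory/topology pairs (DCD+PDB, NetCDF+PRMTOP,
    multi-frame GRO), a synthetic-trajectory generator with programmable
    ground-truth events for validation, and a command-line interface exposing a
    two-step preprocess/map workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ncdf4,
    jsonlite,
    grDevices,
    graphics,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
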
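Package: moltk
Title: Dependency-Light Toolkit for 3D Molecular Structures and Trajectories
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: A small, self-contained toolkit for loading, saving, analyzing
    and manipulating 3D molecular models and molecular-dynamics trajectories.
    Provides a columnar Molecule container with multi-frame coordinates,
    fixed-column PDB and PDBQT readers/writers, a fast binary columnar
    container (PYM), distance-based bond perception with graph operations
    (constituent molecules, branches, bonded neighbours), property-based and
    spatial atom selections, rigid-body translation and rotation about points,
    atoms and lines, inter-molecule alignment (Kabsch), RMSD, steric-clash and
    minimum-distance calculations, molecule merging, and a trajectory
    contact-footprint analysis that writes per-atom contact residence
    fractions into PDB occupancy fields. Includes deterministic synthetic
    fixture generators and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
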
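Package: dbgeom
Title: Geometric Descriptors of Diabody and Fv Interdomain Orientation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Rigid-body geometric analysis of diabody solution structures:
    the four-tryptophan inter-Fv dihedral, the pseudo-dyad diabody angle,
    and unit-sphere projections of domain centers of mass against a
    canonical Fv reference frame; six-measure VH-VL packing descriptors;
    and CDR-loop ensemble analysis by circular dihedral distance,
    average-linkage clustering with medoid extraction, and backbone-torsion
    principal component landscapes. Includes fully specified synthetic
    Fv/diabody generators with analytic ground truth for parameter-recovery
    validation, plus readers for PDB structures and trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
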
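Package: pocketscreen
Title: Structure-First Discovery of Selective Small-Molecule Leads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for structure-first drug discovery screens. Detects
    solvent-accessible surface pockets on protein structures by Delaunay
    tetrahedral decomposition with discrete flow, measures and filters them
    for druggability (area, polar lining, single mouth), compares pocket
    surfaces by shape-distribution statistics (Kolmogorov-Smirnov),
    least-squares superposition with coordinate and orientation RMSD,
    random-alignment null statistics and voxel volume-overlap Tanimoto
    coefficients, filters compound libraries on oral drug-likeness
    descriptors (molecular weight, TPSA, hydrogen-bond donors/acceptors),
    runs hierarchical virtual-screening funnels with pluggable scorers, and
    computes efficacy-ratio selectivity statistics from colony-formation
    screens of cancer cell lines against bone-marrow stem cells, including
    dose-response IC50 estimation. Ships deterministic synthetic-data
    generators for structures, compound libraries and colony tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
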
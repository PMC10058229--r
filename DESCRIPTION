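Package: cytoswitch
Title: Detecting Polymerization-Associated Conformational Switches Across
    Protein Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative structural analysis pipeline for detecting
    conformational switches that accompany filament assembly in
    nucleotide-hydrolyzing protein superfamilies (actins, tubulins and
    their prokaryotic homologs). Parses coordinate files into per-chain
    C-alpha models, places structures into the common column frame of a
    master multiple sequence alignment, collapses redundant depositions
    into representatives by RMSD clustering, finds the structurally
    invariant core by iterative removal of high-variance positions
    (ellipsoid-volume criterion), superposes all structures onto the core
    by iterated mean-reference Kabsch fitting, and performs principal
    component analysis of C-alpha coordinates.  Conformational-state
    annotations (nucleotide state, assembly state, subfamily) are
    correlated with principal component scores via eta-squared and
    permutation tests, and components can be exported as interpolated
    morph trajectories and per-position loading vectors.  Includes a
    synthetic-ensemble generator with a planted assembly-state hinge
    switch so the whole pipeline is testable without structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
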
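Package: pathflow
Title: Current-Flow Allosteric Pathway Analysis of Residue Contact Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds time-averaged, smoothed heavy-atom contact networks from
    molecular dynamics trajectories of membrane proteins, with residue nodes
    and whole-molecule ligand/lipid "interactor" nodes, and computes
    current-flow betweenness ("information flow") from a source residue set to
    a sink residue set by solving the weighted graph Laplacian as a resistor
    network. Includes trajectory observables used alongside flow analysis
    (Kabsch superposition, per-residue RMSF, inter-residue distance
    distributions, hydrogen-bond occupancy, bound-ligand stability), synthetic
    trajectory generators with known ground truth (elastic-network samplers,
    bottleneck and two-path contact systems, a four-condition ligand-occupancy
    series), and a config-driven pipeline that aggregates replicate
    simulations as mean and standard error.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
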
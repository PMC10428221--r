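Package: allopath
Title: Allosteric Pathway Networks and Ensemble-Docking Rescoring for
    Ion-Channel Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds mutual-information/contact weighted residue interaction
    networks from molecular-dynamics trajectories of multi-subunit ion
    channels, and analyses voltage-sensor to pore allosteric communication
    through shortest paths (Dijkstra) and betweenness centrality (Brandes).
    Includes ensemble-docking post-processing (RMSD leader clustering of
    poses, population-weighted MaxP and MaxP-prime rescoring), symmetry-aware
    k-means clustering of receptor conformations with medoid representatives,
    ligand-residue contact fractions and pore-integrity checks, and a
    synthetic-data module that generates pseudo-channel trajectories with
    planted correlation structure and docking pose ensembles with planted
    modes for validation at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
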
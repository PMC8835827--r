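Package: kitdyn
Title: Trajectory Post-Analysis of Multidomain Kinase Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-analysis pipeline for molecular-dynamics trajectories of
    multidomain receptor tyrosine kinases such as KIT, characterizing
    intrinsic and extrinsic disorder of the cytoplasmic region.  Provides
    Kabsch superposition and superposition-normalized deviation metrics
    (RMSD, RMSF, radius of gyration), inter-domain centroid tetrahedra and
    helix bending/kink angles, Kabsch-Sander secondary-structure time maps,
    geometric hydrogen-bond and hydrophobic-contact networks with
    regular-structure exclusion, ensemble-based conformational clustering,
    dynamical cross-correlation maps, backbone principal component analysis,
    elastic-network normal modes, and free-energy landscapes with well
    populations.  A synthetic-trajectory generator with planted multi-state
    dynamics provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
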
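Package: bilayerbind
Title: Peptide-Membrane Binding Analysis for Lipid Bilayer Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analyses of peptide adsorption to lipid bilayers from molecular
    simulation trajectories: residue depth profiles relative to the phosphorus
    plane, closest-residue adsorption timelines, geometric hydrogen-bond
    counting, cutoff Coulomb and Lennard-Jones interaction-energy
    decomposition, electron density profiles, acyl-chain order parameters
    (S_CD), phosphorus-to-phosphorus membrane thickness (global and local),
    area per lipid, and a four-class rotational classifier for the binding
    orientation of an amphipathic helix. Includes a synthetic bilayer and
    helical-peptide generator with scripted adsorption kinematics so every
    analysis can be validated against analytic ground truth without running
    molecular dynamics.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests: jsonlite, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
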
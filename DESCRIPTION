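Package: cortistim
Title: Volume-Conductor and Compartmental-Neuron Modeling of Subdural
    Cortical Stimulation
Version: 0.1.0
Authors@R:
    person("Cortistim", "Developers", email = "cortistim@example.org",
           role = c("aut", "cre"))
Description: Tools for biophysical modeling of subdural cortical stimulation
    (SuCS) of the precentral gyrus. Builds parametric gyral volume-conductor
    geometries (a mirror-symmetric extruded slab and an asymmetric folded
    surrogate), assigns isotropic and fiber-based anisotropic conductivity
    tensors, solves the quasi-static extracellular potential with a
    first-order tetrahedral finite-element method, generates stylized layer 3
    and layer 5 pyramidal-neuron compartmental models, integrates the cable
    equation with active membrane dynamics under extracellular forcing, and
    maps excitation thresholds, action-potential initiation sites, and
    polarity/anisotropy/placement sensitivity across the cortical surface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    graphics,
    grDevices,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
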
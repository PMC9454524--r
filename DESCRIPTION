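Package: cedsim
Title: Convection-Enhanced Co-Delivery of Antiangiogenic and Liposomal
    Cytotoxic Drugs in Heterogeneous Brain Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Image-based multiphysics simulation of convection-enhanced
    delivery (CED) of an antiangiogenic drug co-infused with a liposomal
    cytotoxic drug into a heterogeneous brain tumor.  Provides a synthetic
    DCE-MRI phantom (correlated random tissue-property fields, arterial
    input function, SPGR signal formation), voxelwise tracer-kinetic
    quantification (leaky tracer kinetic model), a quasi-steady
    Darcy-Starling interstitial fluid flow solver, coupled
    convection-diffusion-reaction drug transport with antiangiogenic
    feedback on the microvasculature, and delivery-outcome metrics
    (spatial-averaged concentration, distance courses, distribution
    non-uniformity, effective distribution volume).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    RNifti,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
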
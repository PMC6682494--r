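Package: sweepmri
Title: Continuous Stable-State Swept-Slice MRI Simulation and Respiration-Resolved 4D Sorting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Extended-phase-graph (EPG) simulation of short-TR bSSFP and spoiled
    gradient-echo pulse trains under slice-selective excitation whose centre
    frequency is swept linearly across the volume (the SWEEP acquisition), with
    through-slice motion and flow models, slice-profile analysis metrics, a
    synthetic breathing-abdomen phantom generator, and a respiration-resolved 4D
    sorting pipeline (body-area self-gating, local binning with outlier
    rejection, scattered-to-regular z resampling). Includes an isochromat Bloch
    simulator used as an independent numerical oracle and a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    RNifti,
    EBImage,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
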
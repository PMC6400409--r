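Package: screwkin
Title: Screw-Axis Kinematics of Anatomical Joints from Marker Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Six degree-of-freedom kinematic analysis of anatomical joints
    from rigid marker-cluster trajectories. Provides instantaneous helical
    (screw) axis extraction via Rodrigues parameters, five-point numerical
    differentiation of displacements, least-squares sphere and cylinder
    fitting of articular surfaces, anatomical joint-frame construction from
    the mean flexion axis, Tait-Bryan decomposition of joint displacements
    into rotation and translation curves with Student-t confidence bands,
    and geometric comparison of motion-derived and surface-derived flexion
    axes. A synthetic-experiment generator emulates an in vitro cadaveric
    elbow protocol (optical marker tracking plus surface digitization) so
    that every stage of the pipeline is verifiable by recovery of planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
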
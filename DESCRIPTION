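Package: mpiphantom
Title: Magnetic Particle Imaging Phantom Simulation and Tracer Quantification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing superparamagnetic iron-oxide tracers and
    for simulating and quantifying magnetic particle imaging (MPI) phantom
    experiments. Implements the bimodal lognormal moment-distribution model of
    quasi-static magnetization curves with bounded least-squares fitting,
    equilibrium and relaxation-damped magnetic particle spectroscopy (MPS)
    harmonic simulation, a synthetic field-free-point scanner that voxelizes
    tube phantoms and generates system matrices and noisy frequency-domain
    signals, regularized Kaczmarz image reconstruction, and the downstream
    evaluation protocol: SNR-versus-regularization sweeps, threshold plus
    active-contour segmentation, volume and iron quantification, dual-tube
    selectivity and shadowing metrics, and maximum intensity projections.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    yaml,
    jsonlite,
    RNifti,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
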
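Package: fodinr
Title: Implicit Neural Representations of Fiber Orientation Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous modelling of fiber orientation distributions (FODs)
    from diffusion MRI through the constrained-spherical-deconvolution (CSD)
    forward model. A coordinate network (multi-layer perceptron over a Gaussian
    random Fourier encoding of spatial position) is fitted, unsupervised, to a
    single diffusion-weighted dataset; its output are even-order real
    spherical-harmonic FOD coefficients at any continuous 3D location.
    Single-shell (white matter only) and multi-shell multi-tissue (WM/GM/CSF)
    variants are provided, together with a voxel-wise CSD baseline, a
    brain-like synthetic phantom generator with calibrated Rician noise,
    gradient-table tooling (including greedy angular subsampling), and the
    standard FOD evaluation metrics (angular correlation coefficient, apparent
    fiber density, number of fiber orientations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    pracma,
    jsonlite,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
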
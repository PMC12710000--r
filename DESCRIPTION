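Package: rsaeval
Title: Evaluation of Traced Root System Architectures Against Virtual MRI Ground Truth
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying the accuracy of manually or automatically
    traced plant root system architectures (RSAs). Reads and writes the Root
    System Markup Language (RSML), matches traced roots to a ground-truth
    architecture through a segment distance matrix and an optimal root-level
    assignment under a distance threshold, and computes penalized
    matched-length recall, precision and F1 scores together with standard RSA
    traits (total and average root length, filtered lateral counts,
    inter-lateral distance). Also generates virtual MRI phantoms from an RSA
    by partial-volume capsule voxelization, seeded water noise inside a soil
    cylinder scaled to a target signal-to-noise ratio, and Gaussian
    (Weierstrass) smoothing, plus a parametric generator of faba-bean-like
    root systems and a tracing-error perturbation model for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    xml2,
    jsonlite,
    igraph,
    Matrix,
    RNifti,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
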
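Package: oaentropy
Title: Optic-Axis Entropy Mapping for Polarization-Sensitive OCT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies collagen fiber organization from
    polarization-sensitive optical coherence tomography (PS-OCT) volumes.
    Implements dual-input-state Stokes processing with transverse Gaussian
    filtering, degree-of-polarization maps, local retardance and optic-axis
    extraction by the two-state geometric solution, least-squares fitting of
    the Poincare-sphere plane containing the measured axes, projection to
    scalar orientation angles, and voxel-wise Shannon entropy of those
    angles as a depth-robust measure of dermal fibrosis. A Jones-calculus
    phantom simulator of layered birefringent tissue, including preset
    fibrosis-model cohorts, makes every stage testable without instrument
    data; pipeline utilities cover surface detection, surface-referenced
    depth windows, extreme-mean block selection, cohort statistics and map
    rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
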
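Package: sonomark
Title: Simulation and Analysis of MR-HIFU Sonications Near Biopsy Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study the compatibility of MR-conditional biopsy
    markers with magnetic-resonance-guided high-intensity focused
    ultrasound (MR-HIFU) thermotherapy. Provides a finite-difference
    heat-equation simulator of volumetric circular-trajectory
    sonications, a synthetic gradient-echo image renderer with proton
    resonance frequency (PRF) phase encoding, temperature-dependent T1
    signal decay and susceptibility signal voids, PRF-shift thermometry
    with per-phantom absorption correction, SNR-based masked-voxel
    quantification and infilling, CEM43 thermal-dose volumetry on a
    two-plane 3D reconstruction, and per-sonication summary metrics with
    group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    tools,
    jsonlite,
    RNifti,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
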
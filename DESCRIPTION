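Package: iscatr
Title: Simulation and Analysis of Confocal Interferometric Scattering Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free interferometric scattering (iSCAT)
    microscopy of living cells in wide-field and confocal modes. Implements
    the interferometric image-formation model (reference reflection plus
    coherent scattering, Gouy-phase contrast reversal, confocal axial
    envelope), a phantom generator and forward renderer for membranes,
    tubule networks and diffusing nanoparticles, background estimation and
    contrast mapping, multi-plane 3D interface reconstruction from z-stacks,
    Hessian ridge segmentation, radial-variance-transform particle
    localization with trajectory linking, contrast-calibrated axial tracking,
    and pixelwise persistency and contrast-inversion dynamics maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
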
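Package: dwisegment
Title: Direct White-Matter Tract Segmentation from Diffusion MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments brain white-matter tracts directly from single-shell
    diffusion-weighted MRI, without tractography or fiber-orientation
    modelling. Diffusion measurements are b0-normalized and projected onto an
    order-2 real spherical-harmonics basis (6 coefficient maps), so that any
    subset of at least 6 gradient directions yields a fixed-size input. Random
    well-spread q-space subsets provide train- and test-time augmentation; a
    3D fully convolutional encoder-decoder trained with a soft Dice loss
    predicts per-tract probability maps, and inference averages predictions
    over several measurement subsets. Ensemble disagreement is summarised by
    an unfolded (serpentine) approximation of the earth mover's distance
    between each member and the ensemble mean, giving a scalar statistic that
    flags unreliable segmentations. Includes a multi-tensor phantom simulator
    with Rician noise for end-to-end validation, Dice/HD95/ASSD evaluation
    metrics, and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
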
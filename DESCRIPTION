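Package: xtalfrag
Title: Synthetic Fragment Crystals, Patterson Maps and Volumetric Map Completion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds synthetic crystallographic training data from short peptide
    fragments placed in P1 or P21 unit cells: structure factors by direct
    summation with Cromer-Mann scattering factors, electron-density and
    Patterson maps by FFT synthesis, residue-omitted partial-structure
    template maps, resolution binning, normalization and shape batching.
    Includes evaluation metrics for predicted maps (Pearson map correlation
    over the modelled region, unweighted and figure-of-merit-weighted phase
    errors, sigma-A estimation and weighted map coefficients) and a
    desk-scale hybrid 3D vision-transformer/convolutional model with
    Nystrom approximate attention, trained with a composite
    MSE-minus-Pearson loss on a built-in reverse-mode autodiff tape.
    Reads and writes PDB coordinate files, CCP4/MRC mode-2 maps and a
    plain-text reflection format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
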
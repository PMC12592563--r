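Package: dialibrarian
Title: Experiment-Specific In Silico Spectral Libraries for DIA Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds data-independent-acquisition (DIA) experiment-specific
    in silico spectral libraries. Training data are mined directly from
    chimeric wide-window DIA spectra: matched fragment peaks are screened for
    interference with a dual spectrum-centric / peptide-centric shared-peak
    detector based on extracted-ion-chromatogram correlation and peak-shape
    scoring, and interfered peaks are masked out of the training loss.
    Fragment-ion-intensity (transformer encoder) and retention-time
    (convolution + bidirectional LSTM) models are trained with a masked L1
    objective and used, after in silico tryptic digestion and peptidoform
    expansion, to emit scan-range-filtered, search-engine-compatible library
    tables. Includes a deterministic DIA simulator with injected fragment
    interference, entrapment-based false-discovery-proportion bounds, and
    spectral-entropy collision-energy calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    signal,
    mzR,
    Biostrings,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
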
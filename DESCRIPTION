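Package: unfoldscope
Title: Equilibrium Unfolding Analysis from Time-Resolved Tryptophan Fluorescence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing protein equilibrium unfolding from
    intrinsic tryptophan fluorescence and structural models. Implements global
    reconvolution fitting of multi-wavelength time-correlated single photon
    counting (TCSPC) decays with shared lifetimes, decay-associated spectra,
    double-Boltzmann fitting of denaturant transition curves with derived
    linear-extrapolation thermodynamics, per-tryptophan microenvironment
    descriptors (neighbor counts, polarity, solvent-accessible surface area,
    secondary-structure content, quencher-contact screens) from PDB
    coordinates, tryptophan-tryptophan FRET geometry (orientation factor,
    transfer efficiency, distance distributions over trajectory frames), and
    seedable synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
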
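Package: vsemap
Title: Vibrational Stark Effect and Hydrogen-Bond Blueshift Modeling for
    Nitrile Probes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models nitrile (C=N) stretch frequencies and transition dipole
    moments as a function of local electric field (the vibrational Stark
    effect) plus a hydrogen-bond geometry-dependent blueshift surface
    parameterized by heavy-atom donor distance and angle. Provides
    calibration fits that separate electrostatic and hydrogen-bonding
    contributions, extraction of per-configuration blueshifts, synthetic
    calibration grids and two-state hydrogen-bond dynamics generators, an
    infrared lineshape engine based on the fluctuating frequency
    approximation with an analytic two-site exchange (Kubo) reference,
    hydrogen-bond geometry extraction from PDB structures, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
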
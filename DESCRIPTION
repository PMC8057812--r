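Package: nvjquant
Title: Quantification of Protein Partitioning and Retention at the
    Nucleus-Vacuole Junction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Image and kinetic analysis of inducible enzyme partitioning at
    the yeast nucleus-vacuole junction (NVJ). Provides the NVJ partitioning
    index (ratio of background-subtracted nuclear-envelope line-scan areas
    at the NVJ versus the antipodal envelope), double-normalization of FRAP
    recovery curves, FLIP loss-curve normalization, one-phase exponential
    halftime estimation, growth-resumption curves with a two-sample
    Kolmogorov-Smirnov comparison, a synthetic two-channel microscopy
    renderer with geometric ground truth, and a reaction-diffusion-binding
    simulator of fluorophore kinetics on the nuclear-envelope ring under
    FRAP and FLIP photobleaching schedules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
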
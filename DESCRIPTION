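Package: hexabee
Title: Colour-Hexagon Vision Modelling and Dual-Choice Colour Preference
    Analysis for Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models bee-subjective colour perception with the colour hexagon
    (photoreceptor quantum catches under von Kries background adaptation,
    receptor excitations, hexagon loci, chromatic contrast, spectral purity
    and intensity), encodes the semi-randomised dual-choice test design used
    in stingless-bee colour-preference experiments, and analyses choice
    records with binomial mixed models, Tukey all-pair comparisons and
    classical two-sample tests. Includes a synthetic-data module that
    generates pigment-mixture reflectance spectra and simulated forager
    choices with known ground truth for calibration and parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    multcomp,
    pracma,
    withr,
    jsonlite
Suggests:
    readxl,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
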
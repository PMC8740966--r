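Package: ftirtaxa
Title: Chemometric Discrimination of Plant Taxa from ATR-FTIR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for metabolic fingerprinting of plant material by
    attenuated total reflection Fourier-transform infrared (ATR-FTIR)
    spectroscopy. Implements the standard chemometric pipeline for taxon
    discrimination: fingerprint-region selection, Savitzky-Golay second
    differentiation, vector normalisation and mean-centring; principal
    component analysis, PCA-LDA and cross-validated radial-basis-function
    support vector machines with per-class quality parameters; biomarker
    extraction by peak-picking of PCA loadings with minimum-separation
    suppression and wavenumber lookup; and hierarchical cluster analysis
    of class-mean spectra (Ward linkage, Euclidean distance) in fingerprint
    and loadings-selected input modes, exportable as Newick trees. A
    synthetic spectrum generator with known class, leaf-surface and
    geographic effects provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    readxl
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    ape,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
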
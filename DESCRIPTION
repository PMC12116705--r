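Package: methylassign
Title: Structure-Guided Assignment of Methyl-TROSY NMR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for assigning the Ile, Leu, Val and Met methyl-group
    resonances of large, selectively methyl-labelled proteins. Implements a
    paramagnetic relaxation enhancement (PRE) forward model based on the
    Solomon-Bloembergen equation with HMQC intensity-ratio prediction and
    grid-search spin-label localization; merging of chemical-shift
    predictions from two predictors with uncertainty propagation; expected
    inter-methyl NOE contact networks and cross-peak matching; a formalized
    assignment workflow (point-mutant anchor detection, geminal pairing,
    stereospecific labelling, evidence-weighted greedy propagation,
    minor-form bookkeeping, coverage reporting); side-chain chi2
    dihedral/rotamer geometry; acquisition arithmetic for non-uniform
    sampling and coupling-transfer delays; synthetic ground-truth data
    generators for end-to-end validation; and NMR-STAR 3.1 chemical-shift
    export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
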
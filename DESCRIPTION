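Package: pgsperm
Title: F-Series Prostaglandin Identification and Sperm Guidance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Rule-based identification and quantification of F-series
    prostaglandins from multiple-reaction-monitoring (MRM) chromatograms
    and collision-induced decomposition (CID) product-ion spectra, and
    quantitative sperm-guidance scoring from time-lapse tracks in the
    C. elegans reproductive tract. Ships a reference library of
    chemically synthesized prostaglandin standards and worm compounds,
    diagnostic neutral-loss annotation (z1 loss of 44 Da, dehydrations,
    ring ions m/z 193/191, marker ions m/z 189 and 115), external-standard
    calibration, strain comparison by per-compound fold change, uterine
    zone distribution and motility statistics (velocity, directional
    velocity, reversal frequency), plus synthetic generators for MRM
    traces, CID spectra, calibration series and biased-random-walk sperm
    tracks with retained ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
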
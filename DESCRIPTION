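Package: weanabc
Title: Weaning Age Reconstruction from Bone Collagen Nitrogen Isotopes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconstructs breastfeeding and weaning parameters of past human
    populations from cross-sectional bone collagen nitrogen isotope ratios of
    subadults. Age-dependent bone collagen turnover rates are derived from
    tissue-level bone modeling, remodeling and mineralization physiology;
    delta15N trajectories through the weaning transition are forward-modeled by
    mixing newly synthesized collagen into existing collagen at those rates; and
    the four weaning parameters (ages at the start and end of weaning, the
    maternal-to-infant enrichment factor, and the delta15N of collagen
    synthesized entirely from weaning foods) are inferred by approximate
    Bayesian computation with sequential Monte Carlo sampling and partial
    rejection control. Posteriors are summarized as maximum density estimators
    on 0.1-unit grids, discrete range probabilities, and weighted credible
    intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
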
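Package: itemrel
Title: Item-Score Reliability Estimation for Test Items
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Estimates the reliability of individual item scores within the
    classical test theory framework. Implements four estimators suitable for
    polytomous items: the Molenaar-Sijtsma method (method MS), an item-level
    adaptation of Guttman's lambda-6, the latent class reliability coefficient
    (method LCRC) backed by a built-in EM fitter for unconstrained latent
    class models, and the correction for attenuation (method CA). Also
    provides a multidimensional graded response model simulator, a Monte
    Carlo oracle for population item-score reliability, a bias/variability
    study harness, and the corrected item-rest correlation and Mokken item
    scalability coefficient as companion item indices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
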
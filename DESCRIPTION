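Package: hypofrac
Title: Isoeffect Hypofractionation, Second-Cancer Risk and Plan Comparison
    Tools for Passively Scattered Proton Therapy of the Prostate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form linear-quadratic (LQ) isoeffect conversion between
    photon and proton fractionation regimens with biologically effective dose
    (BED), a constant clinical RBE of 1.1 and alpha/beta uncertainty
    bracketing; neutron equivalent-dose weighting and BEIR VII-style lifetime
    attributable risk estimation for bladder and rectum; static multileaf
    collimator (MLC) leaf fitting to aperture polygons by the edge-midpoint
    rule with scalloping-area error; dose-grid normalization, field
    combination, cumulative DVH and per-organ plan summaries; a
    treatment-calendar cost-savings model for hypofractionation; and seeded
    synthetic generators (opposed-lateral proton dose grids with pelvic
    structure masks, neutron organ-dose tables, aperture polygons) so every
    analysis runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    RNifti,
    withr
Config/testthat/edition: 3
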
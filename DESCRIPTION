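Package: nachrpharm
Title: Subunit-Composition Pharmacology of Insect Nicotinic Receptors
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: Quantitative analysis of how nicotinic acetylcholine receptor
    (nAChR) subunit composition determines agonist potency and efficacy,
    built around two-electrode voltage-clamp concentration-response data
    from Xenopus oocytes. Provides Hill-equation nonlinear least-squares
    fitting of pEC50, Imax and the Hill coefficient; an additive linear
    factor model attributing potency and efficacy to receptor subunits and
    compounds; a CHAID regression tree over subunit presence indicators;
    and a powerset (Hasse) lattice analysis of per-edge pEC50 increments.
    Ships the published Drosophila melanogaster nAChR agonist panel
    (12 core subunit combinations plus 6 substitution receptors, 4 ligands)
    and a synthetic-data generator with known ground truth for end-to-end
    validation of every pipeline stage.
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
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
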
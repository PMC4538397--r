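Package: largetrees
Title: Stand Biomass and Species Dominance from the Largest Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for tropical forest inventory analysis centred on the
    largest trees of a stand. Computes tree-level above-ground biomass (AGB)
    from moist-forest allometric equations with wood-specific-gravity
    assignment and site-specific height-diameter models, builds within-plot
    accumulation curves of AGB and species richness over trees ranked by
    decreasing biomass, fits intercept-free power models predicting total
    plot AGB from the AGB of the N largest trees together with meta-models
    of the coefficients over N, runs site-wise leave-one-out cross-validation,
    and quantifies regional biomass hyperdominance and local dominance of
    species. A multi-site synthetic forest-stand generator with a truncated
    power-law diameter distribution and dominance-skewed species abundances
    makes every stage testable without field data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
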
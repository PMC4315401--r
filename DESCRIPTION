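Package: riverSDM
Title: Presence-Only Habitat Modelling and River-Length Population
    Estimation for Riverine Waterbirds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the wintering population size of riverine
    waterbirds from presence-only records. Derives the 19 standard
    bioclimatic variables from monthly climate grids, fits an
    L1-regularised maximum-entropy (Maxent-style) species distribution
    model over background cells, evaluates it by replicated AUC, jackknife
    and permutation importance, thresholds the averaged suitability map at
    the mean presence probability, intersects the suitable area with an
    order-filtered river network to obtain suitable river length, and
    extrapolates line-transect densities to a population estimate with
    uncertainty. Includes a synthetic-landscape generator with known truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
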
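Package: blmtu
Title: Biotic Ligand Model Toxic Units for Metal Mixture Toxicity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mechanistic analysis of single-metal and metal-mixture
    phytotoxicity bioassays in defined nutrient solutions. Computes inorganic
    aqueous speciation (free ions, hydroxide and carbonate complexes, sulfate
    ion pairs) with Davies activity corrections under a fixed-pH, open-CO2
    regime; fits log-logistic dose-response curves to relative net elongation
    data; estimates biotic ligand model (BLM) binding constants for toxic
    metals, their inorganic complexes and competing magnesium from EC50 series
    across ionic-composition and pH gradients; and evaluates copper-cobalt
    mixture toxicity with toxic units computed either from free-ion activities
    (FIAM) or from biotic-ligand site occupancy (BLM), including additivity
    classification and model comparison. A synthetic-study generator
    reproduces the bioassay design end to end for validation by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
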
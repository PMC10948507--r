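Package: salttol
Title: Salt-Tolerance Evaluation and Mini-Core Collection Construction for
    Phenotyped Germplasm Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for screening germplasm panels for salt tolerance at the
    seedling stage and distilling them into representative mini-core
    collections. Derives 14 salt-tolerance traits (growth-rate stress indices,
    senescence, water contents, shoot/root Na+ and K+ concentrations and their
    ratios) from raw hydroponic phenotype records; fits linear salt-injury
    dose-response curves to recommend a screening NaCl concentration; scores
    genotypes with fuzzy membership functions and a comprehensive D value;
    classifies tolerance into five grades by hierarchical clustering; fits and
    applies a multiple-regression tolerance model; selects a core subset by
    optimizing entry-to-nearest-entry and accession-to-nearest-entry
    objectives over Gower distances with a parallel-tempering search; and
    validates core representativeness (MD%, VD%, CR%, VR%, Shannon-Weaver
    diversity, distribution tests, correlation preservation, PCA). Includes a
    seeded synthetic-data generator emulating the trait moments and
    correlation structure of a 318-genotype Miscanthus panel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    car
Config/testthat/edition: 3
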
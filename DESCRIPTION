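Package: wsrsite
Title: Staged Multi-Criteria Site Selection for Emergency Medical Facilities
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Three-stage screening and ranking of candidate sites for
    temporary emergency medical facilities (Fangcang-style shelter
    hospitals) following the Wuli-Shili-Renli (WSR) systems methodology.
    Stage one excludes candidates violating hard physical constraints;
    stage two ranks survivors by entropy-weighted TOPSIS over objective
    criteria (accessibility potential indices, distance to designated
    hospitals, space scale); stage three ranks the retained fraction by
    interval type-2 trapezoidal fuzzy TOPSIS over expert linguistic
    judgments, with criterion weights elicited through the linear
    Best-Worst Method. Includes criterion calculators, a
    weight-perturbation sensitivity harness, a seeded synthetic case
    generator, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    boot,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
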
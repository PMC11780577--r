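Package: oznoxr
Title: Lipid Double-Bond Regioisomer Annotation from Ozone-Derivatized LC-MS/MS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for annotating and quantifying carbon-carbon double-bond
    (C=C) regioisomers of glycerophospholipids and fatty acids from
    LC-MS/MS runs in which lipids are derivatized in the ion source by
    ozone and nitrogen oxides. Parses lipid shorthand nomenclature,
    computes elemental compositions and adduct m/z values, generates
    theoretical ozonolysis aldehyde and nitrogen-oxide adduct product
    ions with class-specific MS2 fragmentation rules, builds parallel
    reaction monitoring (PRM) target lists, reads mzML or tabular peak
    lists, detects diagnostic ions, enumerates logically consistent
    regioisomer candidates by combinatorial chaining, scores them
    scan-by-scan, and partitions lipid signal into per-isomer relative
    and absolute abundances. A seeded synthetic-run simulator with known
    regioisomer ground truth supports testing without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
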
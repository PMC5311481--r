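Package: tetraturns
Title: Structure-Based Annotation of RNA Tetranucleotide Turns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and annotates RNA tetranucleotide turns (U-turns,
    U_SH-turns, Z-turns and Z_anti-turns) directly from three-dimensional
    coordinates in mmCIF or PDB files. The scheme rests on oxygen-pi stacking
    contacts between backbone oxygens (OP or O4') and nucleobase planes,
    combined with Leontis-Westhof base-pair and base-phosphate hydrogen-bond
    evidence, sugar pseudorotation and glycosidic syn/anti geometry. Includes
    hairpin-loop extraction from tertiary structure, quality and redundancy
    filtering for surveys of structure corpora, count aggregation and
    oxygen-pi distance statistics, and a generator of fully synthetic
    idealized turn structures for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
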
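Package: flynuc
Title: Coarse-Grained Polymer Dynamics of the Drosophila Interphase Nucleus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a beads-on-a-string model of the entire D. melanogaster
    interphase genome at TAD resolution (one bead per pair of homologous
    TADs, four epigenetic bead classes, HET/CEN junction beads and a
    nucleolus), integrates its Langevin dynamics inside a spherical nuclear
    envelope that attracts LAD-containing TADs, and computes the standard
    chromatin-architecture readouts: in-silico Hi-C contact maps, radial
    density profiles, nuclear-envelope layer occupancies, LAD mobility
    statistics and class-class contact sums. Includes a synthetic-genome
    generator reproducing the TAD class and LAD clustering statistics of the
    fly genome, the four experimentally observed nucleus topologies for
    initialization, an 18-nucleus ensemble driver, and the sub-diffusive
    MSD calibration that maps simulation steps onto biological time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    yaml,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
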
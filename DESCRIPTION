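Package: dreissamp
Title: Targeted Metabarcoding Assay Design and Haplotype Typing for
    Dreissenid Mussels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs species- and haplotype-diagnostic amplicon assays from an
    aligned panel of mitochondrial COI haplotypes and applies them to mixed
    template read sets (mock communities, aquarium and field eDNA, bulk
    plankton). Finds conserved degenerate primer windows flanking diagnostic
    cores, computes fixed interspecific differences and the haplotype
    resolvability partition of an amplicon, types merged amplicon reads into
    haplotype-group abundance profiles, and validates quantification against
    known mock-community compositions (observed-versus-expected log-log
    regression, contingency G-tests). Community comparison via Bray-Curtis and
    Kulczynski dissimilarities, NMDS ordination with ANOSIM, and
    minimum-spanning haplotype networks. Includes a seeded synthetic-data
    generator (haplotype panels with planted diagnostics, multinomial read
    simulation with per-base error) and utilities for veliger larval density
    from plankton tow counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
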
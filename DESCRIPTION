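Package: mratax
Title: Multivariate Ratio Analysis and Barcoding Distances for Integrative
    Taxonomy
Version: 0.1.0
Authors@R: person("MRA", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for integrative species delimitation combining
    multivariate ratio analysis (MRA) of linear body measurements with
    DNA-barcoding distance analysis.  Morphometric tools include isometric
    size (isosize), shape principal component analysis in the space of all
    ratios, PCA and allometry ratio spectra with bootstrap confidence
    intervals, and an exhaustive LDA ratio extractor reporting the best
    discriminating character ratio, its standard distance and the
    size-versus-shape measure delta.  Molecular tools include closed-form
    pairwise GTR distances on aligned sequences with pairwise deletion,
    within- and between-OTU barcoding-gap summaries, and simple indel
    coding into binary characters.  Seeded synthetic generators for
    multi-group log-normal measurement tables and GTR-evolved alignments
    make the full pipeline testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
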
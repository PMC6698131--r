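Package: nsltp
Title: Sequence-Structure-Function Analysis of the Plant nsLTP Superfamily
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the plant non-specific lipid transfer protein
    (nsLTP) superfamily. Provides strict family-membership filtering on the
    eight-cysteine motif (8CM), per-clade consensus sequences, a per-column
    Fisher-exact specificity and conservation statistic with
    hue-saturation-value colored alignment rendering, Kabsch-superposition
    RMSD matrices with distance trees, cutoff clustering and medoid
    representatives, real-valued evolutionary-trace (rvET) residue ranking
    with tie-aware rank, coverage and variability tables, cross-cluster
    trace comparison, and seeded synthetic-data generators with planted
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    bio3d,
    jsonlite,
    stats,
    grDevices,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
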
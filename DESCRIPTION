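Package: thinfilament
Title: Integrative Structural, Evolutionary and Clinical Analysis of
    Cardiac Thin-Filament Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking amino-acid variants in the cardiac troponin
    complex to structure and clinical outcome. Maps inter-chain residue
    contacts in thin-filament complexes at a distance cutoff and classifies
    them by calcium state; scores per-site conservation (Jensen-Shannon
    divergence) and selective pressure (counting-based site-specific Ka/Ks
    from back-translated codon alignments); censuses arginine and
    CpG-containing codons and calls recurrent-variant hotspots; runs
    region-stratified cause-specific Kaplan-Meier and log-rank survival
    analyses; computes conformer-ensemble metrics (Kabsch superposition,
    RMSD, RMSF, Shrake-Rupley accessible surface area); and ships synthetic
    generators for complexes, ortholog sets and clinical cohorts so every
    stage runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
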
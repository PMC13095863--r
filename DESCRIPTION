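Package: diveconv
Title: Convergent Amino-Acid Substitution Screening and Selection Scans
    for Diving Waterfowl Comparative Genomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative-genomics screens of lineage-specific
    adaptation in waterfowl: quality control of per-gene codon
    alignments, detection of amino-acid substitutions shared by a
    foreground set of diving species and absent from all background
    species, a counting-based foreground-versus-background dN/dS scan
    with a tip-relabelling permutation null, likelihood-ratio test and
    Benjamini-Hochberg false-discovery-rate machinery for externally
    computed likelihoods, annotation of convergent sites against protein
    domain intervals, hypergeometric term enrichment, and a phylogenetic
    codon/protein sequence simulator with branch-specific dN/dS and
    planted convergent columns for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
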
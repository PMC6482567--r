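Package: famevol
Title: Gene Family Evolution Analysis: Census, Homology, Ka/Ks Selection,
    Phylogeny, Promoter Elements and Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for genome-wide gene-family studies in plants:
    family-member census with protein characterization (length, molecular
    weight, isoelectric point, exon/intron structure), paralog and ortholog
    detection by pairwise local alignment with reciprocal-best-hit logic,
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction,
    duplication dating via T = Ks/2*lambda, sliding-window selection
    profiles, neighbor-joining phylogenies with bootstrap support and
    anchor-based subfamily assignment, promoter cis-element scanning against
    an IUPAC consensus dictionary, 2^-ddCt qPCR quantification and
    tissue-specificity statistics, plus seeded synthetic-data generators
    with ground truth for every stage and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
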
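Package: mascdose
Title: Z-Chromosome Dosage Compensation and Masc Homology Analysis for
    WZ/ZZ Insects
Version: 0.1.0
Authors@R:
    person("mascdose", "developers", email = "mascdose@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting failed Z-chromosome dosage compensation in
    female-heterogametic (WZ/ZZ) insects from pooled-embryo RNA-seq, built
    around the biology of endosymbiont-induced male killing.  Includes a
    seeded negative-binomial simulator of mixed-sex embryo-pool
    transcriptomes under an explicit Z-dose model, protein-level
    homology search (affine-gap Needleman-Wunsch and Smith-Waterman with
    Karlin-Altschul significance) for assigning transcript contigs to
    chromosomes, per-chromosome log2 expression-ratio summaries with a
    permutation test for a Z-specific shift, qPCR relative-dose molecular
    sexing of individuals, and neighbor-joining phylogenetics with
    column-resampling bootstrap for the Masculinizer (Masc) zinc-finger
    domain family.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp (>= 1.0.0),
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
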
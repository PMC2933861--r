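Package: scaffsig
Title: Dinucleotide Signature and DNA Binding-Energy Profiles for Genome
    Assembly Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Windowed genome-composition signals for assessing chromosome
    pseudomolecule assemblies. Computes symmetrized dinucleotide
    relative-abundance signatures (rho*), the coarse-grained signature
    difference delta* between a window and a genome-wide baseline, and
    windowed nearest-neighbor DNA duplex binding-energy and GC-content
    profiles. Overlays profiles with scaffold layouts (AGP or BED) to score
    composition discontinuities at scaffold junctions and to evaluate
    candidate orientation flips, locates centromeric satellite tandem arrays
    by ungapped monomer matching and gap-rule clustering, and provides a
    seeded synthetic-genome generator (Markov backgrounds, LTR-like element
    insertion, satellite arrays, scaffold shredding with known flips) that
    supplies ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    withr,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
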
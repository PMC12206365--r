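Package: VariantScape
Title: Gene-Centric Integration of Sequence Variants, Conservation,
    Phylogeny, Copy Number and Structure
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated, gene-centric analysis toolkit for molecular
    variation in a single protein-coding gene. Harmonizes variant records
    from heterogeneous clinical, somatic and population databases across
    genome builds via block-based liftover, groups DNA variants by protein
    consequence, and classifies population allele frequencies. Computes
    JalView-style per-column conservation metrics (consensus, support,
    occupancy, quality and a 0-11 physicochemical conservation score) from
    a mammalian protein alignment, maps alignment columns to reference
    isoform positions, and annotates human variants with cross-species
    matches. Infers neighbor-joining phylogenies from Poisson/gamma
    corrected protein distances with bootstrap supports. Summarizes
    discrete copy-number calls, gene-versus-arm co-occurrence fractions,
    and Kaplan-Meier / log-rank survival stratified by gene copy loss.
    Detects inter-chain residue contacts in PDB structures with a van der
    Waals overlap criterion, and finds palindromic inverted repeats and
    maximal base pairings in nucleotide sequences. Ships seedable
    synthetic-data generators with ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    survival,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
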
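Package: gzftools
Title: GATA Zinc-Finger Regulon Analysis for Oleaginous Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for regulatory-genomics analysis of fungal GATA zinc-finger
    transcription factors and their regulons, modelled on the nitrogen
    catabolite repression system of Yarrowia lipolytica. Detects and classifies
    spaced-cysteine (Cys-X2-Cys-Xn-Cys-X2-Cys) DNA-interaction domains in
    protein sequences, clusters domain sequences into families by
    neighbor-joining on alignment p-distances, counts IUPAC promoter motifs
    (e.g. GATAA, GYGGGG) on both DNA strands in distance windows around
    transcription start sites, and relates promoter motif content to
    mutant-versus-wild-type expression responses (motif-count binning of log2
    fold changes, gene-set distribution-shift tests, and top-N gene-list
    enrichment with Bonferroni correction). Includes a synthetic-data module
    that generates genomes with planted motifs, expression tables with
    motif-dependent effects, and proteomes with planted domains, all with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
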
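Package: tecompart
Title: Transposable Element Compartmentalization of Gene Flanking Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies TE-compartmentalized genes from gene and repeat
    annotations: computes transposable-element density in the noncoding
    flanking regions of each gene, calls genes in the upper percentiles of
    the per-species density distribution, and characterises the called set
    by GO term enrichment, multigene-family representation, chromosomal
    position (subtelomeric permutation tests), GC and recombination
    context, folded allele-frequency spectra of TE-associated structural
    variants, and aggregation of per-site selection posteriors. Includes a
    synthetic-genome generator that plants each of these signals so the
    whole pipeline can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
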
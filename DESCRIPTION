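Package: intrapop
Title: Intrapopulation Genomics of Single-Species-Dominated Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing intrapopulation genetic variability in
    complete genomes assembled from single-species-dominated metagenomes.
    Detects non-recombinogenic "scrapyard" genome islands from gene-content
    density and GC-skew scatter, calls polymorphic mobile-element insertions
    and gene disruptions from long-read alignments, genotypes insertion
    allele ratios from short-read junction matches, and calls intrapopulation
    short sequence variants (SNVs and short indels) with a transparent pileup
    caller.  Includes an exact Mann-Whitney U test, Nei-Gojobori dN/dS, GC
    skew profiling, and a synthetic population-genome generator with full
    ground truth so every caller can be benchmarked without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
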
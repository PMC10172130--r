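Package: phrscan
Title: Detecting Recombination Between Heterologous Chromosomes from
    Pangenome Homology Mappings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting pseudo-homologous regions (PHRs) --
    stretches where non-homologous chromosomes are nearly identical and
    appear to exchange by recombination -- from segment-level homology
    mappings of assembly contigs against a complete reference. Implements
    best-hit mosaic construction from multi-target untangle hits (identity
    filtering, unreliable-region masking, q-arm anchoring, top-5 ranking
    with anchor-first tie-breaks), regional and positional homology entropy
    (Shannon diversity of best-hit labels and of ordered multi-hit tuples),
    PHR calling by merge-and-filter interval rules, haploid linkage
    disequilibrium decay stratified by region class, Leiden community
    detection on contig homology graphs, cross-assembly base-level
    concordance, and a synthetic-data generator that plants known
    inter-chromosomal exchange for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
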
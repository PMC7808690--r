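Package: clonalsig
Title: Somatic Mutation Signatures and Genome Instability in Clonal Cell Lineages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of somatic genome changes in single cell-derived clonal
    lineages: allele-fraction based clonality filtering of SNV, indel and
    structural-variant calls; trinucleotide-motif mutation-signature
    enrichment with Fisher exact testing and minimum-mutation-load
    estimation; SBS96 and ID83 mutation spectra with signature refitting;
    indel classification into replication-slippage and end-joining classes
    including junction microhomology and templated insertions;
    structural-variant hotspot clustering and common-fragile-site
    colocalization tests; and cohort-level age regressions and group
    comparisons. A seeded synthetic-data generator produces references,
    catalogs and ground truth so the whole pipeline is testable without
    access-controlled sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
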
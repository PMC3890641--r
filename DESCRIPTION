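Package: endofinish
Title: Reference-Guided Finishing and Comparative Analysis of Reduced
    Endosymbiont Genomes
Version: 0.1.0
Authors@R:
    person("endofinish", "maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for finishing small AT-rich bacterial genomes (such as
    those of obligate intracellular endosymbionts) from draft contigs and
    short single-end reads, and for comparing the finished genomes of
    closely related strains.  Contigs are ordered and oriented against a
    collinear reference by unique k-mer synteny, scaffold gaps are closed
    by an overlap-consensus extension that recruits reads on a terminal
    30 bp seed and extends one majority-rule base at a time while
    consuming reads from a repository, low-coverage regions are excised
    and refilled from remapped reads, reference gene models are projected
    and curated (alternate starts, homopolymer frameshifts encoded as
    dual reading-frame models, pseudogene calls), and strain pairs are
    compared by collinear alignment: SNP and indel-event counts,
    synonymous versus nonsynonymous classification under bacterial
    translation table 11, a Wald-Wolfowitz runs test of the positional
    randomness of nonsynonymous changes, and genome composition
    statistics.  A fully parameterised synthetic-genome generator with a
    known truth set makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
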
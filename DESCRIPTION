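Package: decarve
Title: Discovery of Decay-Generated Noncoding RNAs from RNA-Seq Decay Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects decay-generated noncoding RNAs (decRNAs): subgene mRNA
    segments that survive bulk mRNA turnover after transcription shutoff in
    bacteria. Takes strand-specific per-nucleotide coverage from rifampicin
    time-course RNA-seq, finds replicate-consistent stabilized segments with
    a sliding-window rule, and characterizes calls by RNA fold stability,
    RNase E dependence, and Hfq/ProQ co-immunoprecipitation enrichment.
    Includes a synthetic decay-experiment simulator with planted stabilized
    segments so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
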
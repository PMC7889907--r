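Package: taltkit
Title: Discovery of Non-Telomeric ALT Template Elements from Paired-End
    Whole-Genome Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying unique genomic elements that
    are copied into telomeres when telomerase-independent telomere maintenance
    (alternative lengthening of telomeres, ALT) is active.  Implements
    telomeric read classification by TTAGGG/CCCTAA motif counting, anchoring
    of the non-telomeric mates of single-telomeric read pairs with a
    unique-best seed-and-extend aligner, Poisson-based candidate template
    region calling with strand-typed orientation inference, split-read typing
    of head-to-tail tandem junctions, depth-ratio copy number and windowed
    log2-ratio CNV with binary segmentation, pileup-based allelic zygosity and
    longitudinal selection of the amplified template paralog, and in-silico
    restriction digestion.  A built-in simulator of pre-ALT and post-ALT
    diploid toy genomes with machine-readable ground truth supports
    parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    BiocGenerics,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'taltkit-package.R'
    'AllClasses.R'
    'RcppExports.R'
    'accessors.R'
    'utils.R'
    'anchors.R'
    'digest.R'
    'io.R'
    'junctions.R'
    'zygosity.R'
    'quant.R'
    'telreads.R'
    'simulate.R'
    'pipeline.R'
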
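#' @include taltkit-package.R
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' Simulation configuration
#'
#' Parameters of the synthetic diploid genomes and of the paired-end read
#' simulator.  Defaults describe the architecture of an ALT mouse embryonic
#' stem cell line: a ~7.4 kb template element present as two near-identical
#' paralogs (one interstitial, one subterminal behind a short telomere tract),
#' of which exactly one is amplified into tandem head-to-tail telomeric arrays
#' after ALT activation.
#'
#' @slot seed integer; one seed drives every random draw of a simulation.
#' @slot nChromosomes number of chromosomes (diploid: two haplotypes each).
#' @slot chromLength pre-ALT chromosome length in bases.
#' @slot templateLength length of the template element (default 7370, the
#'   inclusive length of the reported mouse chr13 template interval).
#' @slot paralogMarkerCount number of marker SNPs distinguishing the paralogs.
#' @slot telomereUnit canonical telomere repeat unit (G-strand).
#' @slot preAltTelomereLength telomere tract length per end before ALT.
#' @slot altCopiesPerEnd tandem template copies per rebuilt end after ALT.
#' @slot spacerUnits telomere-repeat units between tandem copies (default 8,
#'   the number of units joining the subterminal paralog to the subtelomere).
#' @slot terminalTelomereUnits telomere units appended after the last copy.
#' @slot selectedParalog which paralog ("A" interstitial or "B" subterminal)
#'   seeds the post-ALT arrays; default "B".
#' @slot templateOrientation "forward" or "reverse" insertion of the template
#'   into the arrays, relative to the reference forward strand.
#' @slot readLength,fragmentMean,fragmentSd,coverage,substitutionErrorRate
#'   read simulator parameters (bases, bases, bases, fold, probability).
#' @slot markerMargin template bases at each template end kept marker-free so
#'   junction-spanning reads carry no marker alleles.
#' @export
setClass("SimConfig", slots = c(
  seed = "integer",
  nChromosomes = "integer",
  chromLength = "integer",
  templateLength = "integer",
  paralogMarkerCount = "integer",
  telomereUnit = "character",
  preAltTelomereLength = "integer",
  altCopiesPerEnd = "integer",
  spacerUnits = "integer",
  terminalTelomereUnits = "integer",
  selectedParalog = "character",
  templateOrientation = "character",
  readLength = "integer",
  fragmentMean = "numeric",
  fragmentSd = "numeric",
  coverage = "numeric",
  substitutionErrorRate = "numeric",
  markerMargin = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  pos <- c(nChromosomes = object@nChromosomes, chromLength = object@chromLength,
           templateLength = object@templateLength,
           preAltTelomereLength = object@preAltTelomereLength,
           altCopiesPerEnd = object@altCopiesPerEnd,
           readLength = object@readLength)
  bad <- names(pos)[is.na(pos) | pos <= 0L]
  if (length(bad))
    msg <- c(msg, paste0("fields must be positive: ", paste(bad, collapse = ", ")))
  if (object@spacerUnits < 0L) msg <- c(msg, "spacerUnits must be >= 0")
  if (object@terminalTelomereUnits < 0L)
    msg <- c(msg, "terminalTelomereUnits must be >= 0")
  if (object@paralogMarkerCount < 0L)
    msg <- c(msg, "paralogMarkerCount must be >= 0")
  if (!object@selectedParalog %in% c("A", "B"))
    msg <- c(msg, "selectedParalog must be \"A\" or \"B\"")
  if (!object@templateOrientation %in% c("forward", "reverse"))
    msg <- c(msg, "templateOrientation must be \"forward\" or \"reverse\"")
  if (!grepl("^[ACGT]+$", object@telomereUnit))
    msg <- c(msg, "telomereUnit must be a non-empty A/C/G/T string")
  if (is.na(object@substitutionErrorRate) || object@substitutionErrorRate < 0 ||
      object@substitutionErrorRate > 1)
    msg <- c(msg, "substitutionErrorRate must lie in [0, 1]")
  if (!length(msg) && object@templateLength <= 3L * object@readLength)
    msg <- c(msg, "templateLength must exceed 3 * readLength")
  if (!length(msg) && object@fragmentMean <= 2 * object@readLength)
    msg <- c(msg, "fragmentMean must exceed 2 * readLength")
  if (!length(msg) && object@paralogMarkerCount > 0L &&
      object@templateLength - 2L * object@markerMargin < object@paralogMarkerCount)
    msg <- c(msg, "template too short for the requested marker count and margin")
  if (!length(msg)) {
    # the pre-ALT layout must fit: telomeres, template loci, spacer, and a
    # control interval with 1 kb margins inside the chr1 body
    avail <- object@chromLength - 2L * object@preAltTelomereLength -
      object@templateLength
    body2 <- avail - max(1000L, floor(avail * 0.45))
    if (avail < 2000L || body2 < object@templateLength + 2000L)
      msg <- c(msg, "chromLength too short for telomeres, template and control regions")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated genome
#'
#' Segment-level truth recorded while a synthetic genome is assembled, used by
#' parameter-recovery tests: the ordered segment tiling of every haplotype
#' contig, the template copy number per haploid genome, the selected paralog
#' and its marker table, the expected junction class and orientation call, and
#' per-end telomere-repeat base counts.
#'
#' @slot segments [GenomicRanges::GRanges] tiling each haplotype contig without
#'   gaps or overlaps; `label` is one of subtelomere, telomere_repeat,
#'   template_A, template_B, spacer; strand gives template orientation.
#' @slot copyNumber template segments per haploid genome (segments / ploidy).
#' @slot selectedParalog "A" or "B".
#' @slot markers data.frame: templatePos (1-based within template), alleleA,
#'   alleleB, refContig, refPos (1-based on the mapping reference).
#' @slot expectedJunction "HEAD_TO_TAIL" for post-ALT genomes, "NONE" pre-ALT.
#' @slot expectedOrientation expected [callOrientation()] result.
#' @slot telomereBasesPerEnd named numeric; telomere-repeat bases per contig end.
#' @slot templateRegion,controlRegion single intervals on the mapping
#'   reference: the template locus and an equal-length single-copy control.
#' @slot genomeSize total bases across haplotype contigs.
#' @slot nEnds number of chromosome ends across haplotype contigs.
#' @slot phase "preALT" or "postALT".
#' @export
setClass("SimTruth", slots = c(
  segments = "GRanges",
  copyNumber = "numeric",
  selectedParalog = "character",
  markers = "data.frame",
  expectedJunction = "character",
  expectedOrientation = "character",
  telomereBasesPerEnd = "numeric",
  templateRegion = "GRanges",
  controlRegion = "GRanges",
  genomeSize = "numeric",
  nEnds = "integer",
  phase = "character"
))

setValidity("SimTruth", function(object) {
  seg <- object@segments
  for (ctg in unique(as.character(seqnames(seg)))) {
    s <- seg[seqnames(seg) == ctg]
    s <- s[order(start(s))]
    if (start(s)[1] != 1L)
      return(sprintf("segments of %s do not start at base 1", ctg))
    if (length(s) > 1L && any(start(s)[-1] != head(end(s), -1L) + 1L))
      return(sprintf("segments of %s have gaps or overlaps", ctg))
  }
  nt <- sum(grepl("^template_", seg$label))
  if (abs(object@copyNumber - nt / 2) > 1e-8)
    return("copyNumber is not template segment count / ploidy")
  TRUE
})

#' A simulated ALT study genome
#'
#' Bundle of the diploid haplotype sequences, the haploid mapping reference
#' (which, like a real reference assembly, carries a single template copy),
#' the generating configuration and the [SimTruth-class] record.
#'
#' @slot config the [SimConfig-class] used.
#' @slot phase "preALT" or "postALT".
#' @slot genome [Biostrings::DNAStringSet] of haplotype contigs.
#' @slot reference [Biostrings::DNAStringSet] mapping reference.
#' @slot truth [SimTruth-class].
#' @export
setClass("AltSimulation", slots = c(
  config = "SimConfig",
  phase = "character",
  genome = "DNAStringSet",
  reference = "DNAStringSet",
  truth = "SimTruth"
))

#' Paired-end reads
#'
#' Mate sequences of simulated (or imported) read pairs.  Qualities follow a
#' constant-quality model (one Phred+33 character applied to every base);
#' downstream classification ignores qualities.
#'
#' @slot mate1,mate2 [Biostrings::DNAStringSet]; names are shared pair ids.
#' @slot qualityChar single Phred+33 quality character (default "?", Q30).
#' @export
setClass("PairedReads", slots = c(
  mate1 = "DNAStringSet",
  mate2 = "DNAStringSet",
  qualityChar = "character"
))

setValidity("PairedReads", function(object) {
  if (length(object@mate1) != length(object@mate2))
    return("mate1 and mate2 differ in length")
  if (!identical(names(object@mate1), names(object@mate2)))
    return("mate ids differ between mates")
  if (length(object@qualityChar) != 1L || nchar(object@qualityChar) != 1L)
    return("qualityChar must be a single character")
  TRUE
})

#' Genome-wide telomere content estimate
#'
#' Coverage-normalised telomere length: `lengthPerEnd = telomericBases /
#' (meanDepth * nEnds)` with `meanDepth = totalBases / genomeSize`.
#'
#' @slot telomericBases,totalBases,genomeSize,meanDepth,lengthPerEnd numeric.
#' @slot nEnds integer number of chromosome ends.
#' @export
setClass("TelomereContentEstimate", slots = c(
  telomericBases = "numeric",
  totalBases = "numeric",
  genomeSize = "numeric",
  nEnds = "integer",
  meanDepth = "numeric",
  lengthPerEnd = "numeric"
))

#' Seed index over a reference
#'
#' Canonical k-mer index used by [mapReads()].  Holds an external pointer to
#' the native index; rebuild with [buildSeedIndex()] rather than serialising.
#'
#' @slot ptr external pointer to the native index.
#' @slot k k-mer size.
#' @slot maxOcc k-mers occurring more often than this are not seeds.
#' @slot seqnames,seqlengths contig names and lengths.
#' @slot mappableLength non-N reference bases.
#' @slot nKmers,nPositions index size statistics.
#' @export
setClass("SeedIndex", slots = c(
  ptr = "externalptr",
  k = "integer",
  maxOcc = "integer",
  seqnames = "character",
  seqlengths = "integer",
  mappableLength = "numeric",
  nKmers = "numeric",
  nPositions = "numeric"
))

#' Depth-ratio copy number estimate
#'
#' Copy number of a target interval expressed relative to a single-copy
#' control interval: `ratio = meanDepthTarget / meanDepthControl`, i.e.
#' copies per haploid genome when the control is single-copy.
#'
#' @slot target,control the intervals ([GenomicRanges::GRanges], length 1).
#' @slot meanDepthTarget,meanDepthControl,ratio numeric.
#' @export
setClass("CopyNumberEstimate", slots = c(
  target = "GRanges",
  control = "GRanges",
  meanDepthTarget = "numeric",
  meanDepthControl = "numeric",
  ratio = "numeric"
))

setValidity("CopyNumberEstimate", function(object) {
  if (object@meanDepthControl <= 0) return("control interval depth must be > 0")
  if (abs(object@ratio - object@meanDepthTarget / object@meanDepthControl) > 1e-8)
    return("ratio does not equal meanDepthTarget / meanDepthControl")
  TRUE
})

#' Two-sample CNV profile
#'
#' Windowed, library-size-normalised log2 depth ratios between a test and a
#' reference sample, plus (after [segmentProfile()]) a segmentation.
#'
#' @slot window window size in bases.
#' @slot windows [GenomicRanges::GRanges] with `log2Ratio`, `testBases`,
#'   `refBases` per window.
#' @slot segments [GenomicRanges::GRanges] with `meanLog2` and `nWindows`, or
#'   NULL before segmentation.
#' @export
setClass("CnvProfile", slots = c(
  window = "integer",
  windows = "GRanges",
  segments = "GRangesOrNULL"
))

#' Restriction enzyme
#'
#' @slot name enzyme name.
#' @slot pattern recognition pattern over A/C/G/T/N (N matches any base).
#' @slot cutOffset cut position in bases from the pattern start.
#' @export
setClass("Enzyme", slots = c(
  name = "character",
  pattern = "character",
  cutOffset = "integer"
))

setValidity("Enzyme", function(object) {
  if (!grepl("^[ACGTN]+$", object@pattern))
    return("pattern must be over A/C/G/T/N")
  if (object@cutOffset < 0L || object@cutOffset > nchar(object@pattern))
    return("cutOffset must lie within [0, pattern length]")
  TRUE
})

#' In-silico digestion result
#'
#' @slot enzymes names of the enzymes applied.
#' @slot cuts strictly increasing 0-based cut positions.
#' @slot fragments fragment lengths; they sum to the input length.
#' @slot seqLength input sequence length.
#' @export
setClass("DigestResult", slots = c(
  enzymes = "character",
  cuts = "numeric",
  fragments = "numeric",
  seqLength = "numeric"
))

setValidity("DigestResult", function(object) {
  if (is.unsorted(object@cuts, strictly = TRUE)) return("cuts must be strictly increasing")
  if (length(object@fragments) && abs(sum(object@fragments) - object@seqLength) > 1e-8)
    return("fragment lengths do not sum to the sequence length")
  TRUE
})

#' Longitudinal paralog selection result
#'
#' Which template paralog was amplified, from per-timepoint paralog allele
#' frequencies (AF) at marker sites plus copy-number ratios.  Paralog p is
#' selected when its AF shift `S_p = AF_p(last) - AF_p(first)` is at least
#' `minShift`, `AF_p(last)` is at least `minFinalAf`, and the copy-number
#' ratio is non-decreasing over time.
#'
#' @slot trajectory data.frame: timepoint, afA, afB, cnRatio.
#' @slot scoreA,scoreB AF shifts of the two paralogs.
#' @slot selected "A", "B" or "none".
#' @export
setClass("ParalogSelectionResult", slots = c(
  trajectory = "data.frame",
  scoreA = "numeric",
  scoreB = "numeric",
  selected = "character"
))

#' Pipeline configuration
#'
#' Validated stage parameters for [runPipeline()].  Every parameter has a
#' default, so an empty configuration file is valid.
#'
#' @slot seed global seed; per-stage seeds are derived from it.
#' @slot outdir output directory or NA for in-memory results only.
#' @slot simulation [SimConfig-class] for the built-in simulator.
#' @slot params named list of per-stage parameter lists.
#' @export
setClass("PipelineConfig", slots = c(
  seed = "integer",
  outdir = "character",
  simulation = "SimConfig",
  params = "list"
))
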
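#' @include AllClasses.R
NULL

#' Accessors for taltkit objects
#'
#' Small accessor generics exposing slots of the package's S4 classes.
#'
#' @param x an object of the documented class.
#' @return See each method.
#' @name taltkit-accessors
NULL

#' @rdname taltkit-accessors
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))
#' @rdname taltkit-accessors
#' @export
setMethod("simTruth", "AltSimulation", function(x) x@truth)

#' @rdname taltkit-accessors
#' @export
setGeneric("genomeSequences", function(x) standardGeneric("genomeSequences"))
#' @rdname taltkit-accessors
#' @export
setMethod("genomeSequences", "AltSimulation", function(x) x@genome)

#' @rdname taltkit-accessors
#' @export
setGeneric("referenceSequences", function(x) standardGeneric("referenceSequences"))
#' @rdname taltkit-accessors
#' @export
setMethod("referenceSequences", "AltSimulation", function(x) x@reference)

#' @rdname taltkit-accessors
#' @export
setGeneric("truthSegments", function(x) standardGeneric("truthSegments"))
#' @rdname taltkit-accessors
#' @export
setMethod("truthSegments", "SimTruth", function(x) x@segments)
#' @rdname taltkit-accessors
#' @export
setMethod("truthSegments", "AltSimulation", function(x) x@truth@segments)

#' @rdname taltkit-accessors
#' @export
setGeneric("markerSites", function(x) standardGeneric("markerSites"))
#' @rdname taltkit-accessors
#' @export
setMethod("markerSites", "SimTruth", function(x) x@markers)
#' @rdname taltkit-accessors
#' @export
setMethod("markerSites", "AltSimulation", function(x) x@truth@markers)

#' @rdname taltkit-accessors
#' @export
setGeneric("copyRatio", function(x) standardGeneric("copyRatio"))
#' @rdname taltkit-accessors
#' @export
setMethod("copyRatio", "CopyNumberEstimate", function(x) x@ratio)

#' @rdname taltkit-accessors
#' @export
setGeneric("fragmentLengths", function(x) standardGeneric("fragmentLengths"))
#' @rdname taltkit-accessors
#' @export
setMethod("fragmentLengths", "DigestResult", function(x) x@fragments)

#' @rdname taltkit-accessors
#' @export
setGeneric("cutPositions", function(x) standardGeneric("cutPositions"))
#' @rdname taltkit-accessors
#' @export
setMethod("cutPositions", "DigestResult", function(x) x@cuts)

#' @rdname taltkit-accessors
#' @export
setGeneric("lengthPerEnd", function(x) standardGeneric("lengthPerEnd"))
#' @rdname taltkit-accessors
#' @export
setMethod("lengthPerEnd", "TelomereContentEstimate", function(x) x@lengthPerEnd)

#' @rdname taltkit-accessors
#' @export
setGeneric("selectedParalog", function(x) standardGeneric("selectedParalog"))
#' @rdname taltkit-accessors
#' @export
setMethod("selectedParalog", "ParalogSelectionResult", function(x) x@selected)
#' @rdname taltkit-accessors
#' @export
setMethod("selectedParalog", "SimTruth", function(x) x@selectedParalog)

#' @rdname taltkit-accessors
#' @export
setGeneric("cnvSegments", function(x) standardGeneric("cnvSegments"))
#' @rdname taltkit-accessors
#' @export
setMethod("cnvSegments", "CnvProfile", function(x) x@segments)

#' @rdname taltkit-accessors
#' @export
setMethod("length", "PairedReads", function(x) length(x@mate1))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig\n")
  cat(sprintf("  seed %d | %d chromosome(s) of %s bp, diploid\n",
              object@seed, object@nChromosomes,
              format(object@chromLength, big.mark = ",")))
  cat(sprintf("  template %d bp, %d marker SNP(s), selected paralog %s (%s)\n",
              object@templateLength, object@paralogMarkerCount,
              object@selectedParalog, object@templateOrientation))
  cat(sprintf("  telomeres: unit %s, pre-ALT %d bp; ALT arrays: %d copies/end, %d-unit spacers\n",
              object@telomereUnit, object@preAltTelomereLength,
              object@altCopiesPerEnd, object@spacerUnits))
  cat(sprintf("  reads: %d bp pairs, fragments %.0f+/-%.0f, %gx, error %g\n",
              object@readLength, object@fragmentMean, object@fragmentSd,
              object@coverage, object@substitutionErrorRate))
})

setMethod("show", "AltSimulation", function(object) {
  cat(sprintf("AltSimulation (%s)\n", object@phase))
  cat(sprintf("  genome: %d haplotype contig(s), %s bp total\n",
              length(object@genome),
              format(sum(Biostrings::width(object@genome)), big.mark = ",")))
  cat(sprintf("  reference: %d contig(s), %s bp\n", length(object@reference),
              format(sum(Biostrings::width(object@reference)), big.mark = ",")))
  cat(sprintf("  truth: copy number %.1f per haploid genome, paralog %s, junction %s\n",
              object@truth@copyNumber, object@truth@selectedParalog,
              object@truth@expectedJunction))
})

setMethod("show", "PairedReads", function(object) {
  cat(sprintf("PairedReads: %s pairs, constant quality '%s'\n",
              format(length(object), big.mark = ","), object@qualityChar))
})

setMethod("show", "TelomereContentEstimate", function(object) {
  cat("TelomereContentEstimate\n")
  cat(sprintf("  telomeric bases %s of %s total (mean depth %.2fx over %s bp)\n",
              format(object@telomericBases, big.mark = ","),
              format(object@totalBases, big.mark = ","),
              object@meanDepth, format(object@genomeSize, big.mark = ",")))
  cat(sprintf("  length per end (%d ends): %.0f bp\n",
              object@nEnds, object@lengthPerEnd))
})

setMethod("show", "SeedIndex", function(object) {
  cat(sprintf("SeedIndex: k=%d over %d contig(s) (%s mappable bp), %s k-mers / %s positions (maxOcc %d)\n",
              object@k, length(object@seqnames),
              format(object@mappableLength, big.mark = ","),
              format(object@nKmers, big.mark = ","),
              format(object@nPositions, big.mark = ","), object@maxOcc))
})

setMethod("show", "CopyNumberEstimate", function(object) {
  cat("CopyNumberEstimate\n")
  cat(sprintf("  target  %s:%d-%d  mean depth %.2f\n",
              as.character(seqnames(object@target)), start(object@target),
              end(object@target), object@meanDepthTarget))
  cat(sprintf("  control %s:%d-%d  mean depth %.2f\n",
              as.character(seqnames(object@control)), start(object@control),
              end(object@control), object@meanDepthControl))
  cat(sprintf("  ratio (copies per haploid genome): %.3f\n", object@ratio))
})

setMethod("show", "CnvProfile", function(object) {
  cat(sprintf("CnvProfile: %d windows of %d bp", length(object@windows),
              object@window))
  if (!is.null(object@segments))
    cat(sprintf(", %d segment(s)", length(object@segments)))
  cat("\n")
})

setMethod("show", "Enzyme", function(object) {
  pat <- object@pattern
  cat(sprintf("Enzyme %s: %s^%s\n", object@name,
              substr(pat, 1, object@cutOffset),
              substr(pat, object@cutOffset + 1L, nchar(pat))))
})

setMethod("show", "DigestResult", function(object) {
  cat(sprintf("DigestResult (%s): %d cut(s), %d fragment(s) over %s bp\n",
              paste(object@enzymes, collapse = "+"), length(object@cuts),
              length(object@fragments),
              format(object@seqLength, big.mark = ",")))
})

setMethod("show", "ParalogSelectionResult", function(object) {
  cat(sprintf("ParalogSelectionResult: selected %s (S_A=%.3f, S_B=%.3f)\n",
              object@selected, object@scoreA, object@scoreB))
  print(object@trajectory, row.names = FALSE)
})

setMethod("show", "PipelineConfig", function(object) {
  cat(sprintf("PipelineConfig: seed %d, outdir %s\n", object@seed,
              ifelse(is.na(object@outdir), "<in-memory>", object@outdir)))
})
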
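#' @include AllClasses.R utils.R
NULL

#' Pileup allele depths at marker sites
#'
#' Counts reference/alternative/other base observations at each site from
#' ungapped read placements.  For a minus-strand placement the stored read is
#' the sequence as sequenced, so the base reported at reference position p is
#' the complement of the read base at offset `end - p` from the read start.
#'
#' @param hits [GenomicRanges::GRanges] placements with a `readId` column
#'   (from [mapReads()]).
#' @param readSeqs read sequences named by read id (character or
#'   [Biostrings::DNAStringSet]).
#' @param sites [GenomicRanges::GRanges] of single-base sites with metadata
#'   columns `refAllele`, `altAllele` (and optionally `paralog`).
#' @return [S4Vectors::DataFrame], one row per site: contig, pos, refAllele,
#'   altAllele, paralog (NA when absent), refDepth, altDepth, otherDepth.
#' @export
pileupAlleles <- function(hits, readSeqs, sites) {
  if (is(readSeqs, "XStringSet")) readSeqs <- as.character(readSeqs)
  if (is.null(names(readSeqs))) stop("readSeqs must be named by read id")
  sl <- seqlengths(hits)
  pos <- start(sites)
  ctg <- as.character(seqnames(sites))
  known <- !is.na(sl[ctg])
  if (any(known & (pos < 1L | pos > sl[ctg])))
    .stopData("site outside contig bounds")
  refD <- altD <- othD <- integer(length(sites))
  ov <- findOverlaps(sites, hits)
  sHit <- S4Vectors::subjectHits(ov)
  qHit <- S4Vectors::queryHits(ov)
  if (length(ov)) {
    seqs <- readSeqs[hits$readId[sHit]]
    hs <- start(hits)[sHit]
    he <- end(hits)[sHit]
    neg <- as.character(strand(hits))[sHit] == "-"
    p <- pos[qHit]
    off <- ifelse(neg, he - p + 1L, p - hs + 1L)
    base <- substr(seqs, off, off)
    base[neg] <- .compBase(base[neg])
    base <- toupper(base)
    refA <- sites$refAllele[qHit]
    altA <- sites$altAllele[qHit]
    isRef <- base == refA
    isAlt <- base == altA
    refD <- as.integer(tabulate(qHit[isRef], nbins = length(sites)))
    altD <- as.integer(tabulate(qHit[isAlt], nbins = length(sites)))
    othD <- as.integer(tabulate(qHit[!isRef & !isAlt], nbins = length(sites)))
  }
  DataFrame(contig = ctg, pos = pos,
            refAllele = sites$refAllele, altAllele = sites$altAllele,
            paralog = if (is.null(sites$paralog)) NA_character_ else sites$paralog,
            refDepth = refD, altDepth = altD, otherDepth = othD)
}

#' Call allelic zygosity from allele depths
#'
#' NOCALL when `refDepth + altDepth < minDepth`; otherwise HOM_ALT when the
#' alternative allele frequency exceeds `homCut`, HOM_REF when it falls below
#' `1 - homCut`, HET in between.
#'
#' @param depths [S4Vectors::DataFrame] from [pileupAlleles()] (needs
#'   `refDepth` and `altDepth`).
#' @param minDepth minimum allele depth for a call (default 5).
#' @param homCut homozygosity threshold on allele frequency (default 0.9).
#' @return The input with `altFrequency` and `call` columns appended.
#' @export
callZygosity <- function(depths, minDepth = 5L, homCut = 0.9) {
  tot <- depths$refDepth + depths$altDepth
  af <- ifelse(tot > 0L, depths$altDepth / tot, NA_real_)
  call <- rep("NOCALL", nrow(depths))
  ok <- tot >= minDepth
  call[ok & af > homCut] <- "HOM_ALT"
  call[ok & af < 1 - homCut] <- "HOM_REF"
  call[ok & af >= 1 - homCut & af <= homCut] <- "HET"
  out <- depths
  out$altFrequency <- af
  out$call <- call
  out
}

#' Homozygous fraction by distance from the chromosome end
#'
#' Bins zygosity calls by distance from the distal chromosome end and reports
#' the homozygous fraction `HOM / (HOM + HET)` per bin -- the subtelomeric
#' loss-of-heterozygosity gradient.  NOCALLs are ignored; empty bins are NA.
#'
#' @param calls [S4Vectors::DataFrame] from [callZygosity()]; all rows must
#'   lie on one contig (`pos` column used).
#' @param chromLength contig length in bases.
#' @param bin bin size in bases (default 100000).
#' @param fromEnd `"right"` (q-arm, default) or `"left"`: which end distance
#'   is measured from.
#' @return data.frame: distanceStart, distanceEnd (bases from the end), n
#'   (calls in bin) and homFraction, ordered from the end inward.
#' @export
lohGradient <- function(calls, chromLength, bin = 100000L,
                        fromEnd = c("right", "left")) {
  fromEnd <- match.arg(fromEnd)
  if (length(unique(calls$contig)) > 1L)
    stop("calls must lie on a single contig")
  used <- calls[calls$call != "NOCALL", , drop = FALSE]
  dist <- if (fromEnd == "right") chromLength - used$pos else used$pos - 1L
  nBins <- ceiling(chromLength / bin)
  idx <- pmin(floor(dist / bin) + 1L, nBins)
  hom <- used$call %in% c("HOM_REF", "HOM_ALT")
  n <- tabulate(idx, nbins = nBins)
  nHom <- tabulate(idx[hom], nbins = nBins)
  data.frame(distanceStart = (seq_len(nBins) - 1L) * bin,
             distanceEnd = pmin(seq_len(nBins) * bin, chromLength),
             n = n,
             homFraction = ifelse(n > 0L, nHom / n, NA_real_))
}

# Mean private-allele frequency of a paralog across labelled marker sites:
# at a site whose alternative allele is private to paralog p, AF_p is the
# alt frequency; at a site labelled with the other paralog it is 1 - alt.
.paralogAf <- function(calls, paralog) {
  lab <- calls$paralog
  ok <- !is.na(lab) & lab %in% c("A", "B") & !is.na(calls$altFrequency)
  if (!any(ok)) return(NA_real_)
  af <- ifelse(lab[ok] == paralog, calls$altFrequency[ok],
               1 - calls$altFrequency[ok])
  mean(af)
}

#' Select the amplified template paralog from a longitudinal series
#'
#' Because near-identical template copies cross-map to one reference locus,
#' the pileup there pools both paralogs and the frequency of a
#' paralog-private allele tracks that paralog's share of the template dosage.
#' For each paralog p the mean private-allele frequency `AF_p` is computed
#' per timepoint and the selection score is `S_p = AF_p(last) - AF_p(first)`.
#' Paralog p is selected when `S_p >= minShift`, `AF_p(last) >= minFinalAf`,
#' and the copy-number ratio is non-decreasing over the series (within
#' `cnTolerance` relative slack); otherwise the result is "none".
#'
#' @param callsList list of per-timepoint zygosity calls ([callZygosity()])
#'   at paralog-labelled marker sites, in population-doubling order.
#' @param cnRatios numeric vector of per-timepoint copy-number ratios (same
#'   length/order), or a list of [CopyNumberEstimate-class].
#' @param minShift minimum AF shift (default 0.25).
#' @param minFinalAf minimum final AF of the selected paralog (default 0.75).
#' @param cnTolerance relative tolerance on copy-number monotonicity
#'   (default 0.05).
#' @return A [ParalogSelectionResult-class].
#' @export
selectAmplifiedParalog <- function(callsList, cnRatios, minShift = 0.25,
                                   minFinalAf = 0.75, cnTolerance = 0.05) {
  if (length(callsList) < 2L) stop("at least two timepoints are required")
  if (is.list(cnRatios) && !is.numeric(cnRatios))
    cnRatios <- vapply(cnRatios, copyRatio, numeric(1))
  if (length(cnRatios) != length(callsList))
    stop("cnRatios must match the number of timepoints")
  hasLabels <- any(vapply(callsList, function(x)
    any(!is.na(x$paralog) & x$paralog %in% c("A", "B")), logical(1)))
  if (!hasLabels) stop("no paralog-labelled marker sites provided")
  afA <- vapply(callsList, .paralogAf, numeric(1), paralog = "A")
  afB <- vapply(callsList, .paralogAf, numeric(1), paralog = "B")
  nT <- length(callsList)
  scoreA <- afA[nT] - afA[1]
  scoreB <- afB[nT] - afB[1]
  cnOk <- all(diff(cnRatios) >= -cnTolerance * head(cnRatios, -1L))
  selected <- "none"
  if (cnOk) {
    candA <- !is.na(scoreA) && scoreA >= minShift && afA[nT] >= minFinalAf
    candB <- !is.na(scoreB) && scoreB >= minShift && afB[nT] >= minFinalAf
    if (candA && (!candB || scoreA >= scoreB)) selected <- "A"
    else if (candB) selected <- "B"
  }
  new("ParalogSelectionResult",
      trajectory = data.frame(timepoint = seq_len(nT), afA = afA, afB = afB,
                              cnRatio = cnRatios),
      scoreA = scoreA, scoreB = scoreB, selected = selected)
}
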
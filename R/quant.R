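#' @include AllClasses.R utils.R
NULL

#' Per-base depth from anchor placements
#'
#' @param hits [GenomicRanges::GRanges] of read placements (with seqlengths
#'   set, as returned by [mapReads()]), or any interval set.
#' @param seqlengths optional named integer vector overriding the hit
#'   seqlengths.
#' @return [IRanges::RleList] of per-base depths, one element per contig; the
#'   sum over all contigs equals the total aligned bases.
#' @export
depthFromAnchors <- function(hits, seqlengths = NULL) {
  sl <- if (is.null(seqlengths)) seqlengths(hits) else seqlengths
  if (any(is.na(sl))) .stopData("contig lengths are unknown; supply seqlengths")
  bad <- start(hits) < 1L | end(hits) > sl[as.character(seqnames(hits))]
  if (any(bad)) .stopData(sum(bad), " hit(s) fall outside contig bounds")
  coverage(hits, width = sl)
}

.meanDepth <- function(depth, region) {
  ctg <- as.character(seqnames(region))
  if (!ctg %in% names(depth)) .stopData("interval contig absent from depth track")
  rle <- depth[[ctg]]
  if (end(region) > length(rle) || start(region) < 1L)
    .stopData("interval out of contig bounds")
  v <- Views(rle, start = start(region), end = end(region))
  sum(viewSums(v)) / sum(width(region))
}

#' Depth-ratio copy number
#'
#' Copy number of a target interval relative to a single-copy control
#' interval: the ratio of their mean read depths.  With a single-copy
#' control, the ratio reads as copies per haploid genome; a two-locus
#' homozygous template reads ~2.
#'
#' @param depth an [IRanges::RleList] depth track ([depthFromAnchors()]).
#' @param target,control intervals ([GenomicRanges::GRanges], length 1).
#' @return A [CopyNumberEstimate-class].
#' @export
copyNumberRatio <- function(depth, target, control) {
  mt <- .meanDepth(depth, target)
  mc <- .meanDepth(depth, control)
  if (mc <= 0) stop("insufficient data: control interval has zero depth")
  new("CopyNumberEstimate", target = target, control = control,
      meanDepthTarget = mt, meanDepthControl = mc, ratio = mt / mc)
}

#' Windowed log2 depth ratio between two samples
#'
#' Library-size-normalised per-window log2 ratios: for window i with base
#' sums `t_i` and `r_i` and genome-wide totals `T` and `R`,
#' `log2(((t_i + pc) / T) / ((r_i + pc) / R))`.  Windows are half-open tiles
#' of the shared contigs; the last partial window is kept.
#'
#' @param test,ref depth tracks ([IRanges::RleList]) over the same contigs.
#' @param window window size in bases (default 1000).
#' @param pseudocount added to each window sum (default 0.5).
#' @return A [CnvProfile-class] (no segments yet; see [segmentProfile()]).
#' @export
windowedLog2Ratio <- function(test, ref, window = 1000L, pseudocount = 0.5) {
  if (!identical(sort(names(test)), sort(names(ref))) ||
      !all(lengths(test)[names(test)] == lengths(ref)[names(test)]))
    .stopData("test and ref depth tracks cover different contigs")
  sl <- setNames(as.integer(lengths(test)), names(test))
  tiles <- tileGenome(sl, tilewidth = window, cut.last.tile.in.chrom = TRUE)
  tSum <- rSum <- numeric(length(tiles))
  for (ctg in names(sl)) {
    sel <- as.character(seqnames(tiles)) == ctg
    v <- Views(test[[ctg]], start = start(tiles)[sel], end = end(tiles)[sel])
    tSum[sel] <- viewSums(v)
    v <- Views(ref[[ctg]], start = start(tiles)[sel], end = end(tiles)[sel])
    rSum[sel] <- viewSums(v)
  }
  totT <- sum(tSum); totR <- sum(rSum)
  if (totT <= 0 || totR <= 0) .stopData("a depth track is empty")
  lr <- log2(((tSum + pseudocount) / totT) / ((rSum + pseudocount) / totR))
  tiles$log2Ratio <- lr
  tiles$testBases <- tSum
  tiles$refBases <- rSum
  new("CnvProfile", window = as.integer(window), windows = tiles,
      segments = NULL)
}

# Best single breakpoint of x under the residual-sum-of-squares criterion,
# honouring the minimum segment length.  Returns list(split, reduction) where
# split is the last index of the left part, or NULL when no split is allowed.
.bestSplit <- function(x, minSegment) {
  n <- length(x)
  if (n < 2L * minSegment) return(NULL)
  cs <- cumsum(x)
  j <- minSegment:(n - minSegment)
  n1 <- j
  n2 <- n - j
  m1 <- cs[j] / n1
  m2 <- (cs[n] - cs[j]) / n2
  # RSS reduction of splitting at j: n1*n2/n * (m1 - m2)^2
  red <- n1 * n2 / n * (m1 - m2)^2
  best <- which.max(red)
  list(split = j[best], reduction = red[best])
}

.segmentVector <- function(x, minSegment, penalty) {
  segs <- list(c(1L, length(x)))
  out <- list()
  while (length(segs)) {
    rg <- segs[[1]]
    segs <- segs[-1]
    xs <- x[rg[1]:rg[2]]
    sp <- .bestSplit(xs, minSegment)
    if (!is.null(sp) && sp$reduction > penalty) {
      segs <- c(list(c(rg[1], rg[1] + sp$split - 1L),
                     c(rg[1] + sp$split, rg[2])), segs)
    } else {
      out[[length(out) + 1L]] <- rg
    }
  }
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Segment a CNV profile by recursive binary segmentation
#'
#' Recursively splits each contig's window series at the breakpoint giving
#' the largest between-segment residual-sum-of-squares reduction, accepting a
#' split only when the reduction exceeds a penalty (default `2 * var * log n`,
#' a BIC-style cost with the noise variance estimated robustly from successive
#' window differences).  Segments never fall below `minSegment` windows.
#' This is a simple changepoint scheme, not circular binary segmentation; it
#' is adequate for the step-like profiles of tandem amplifications.
#'
#' @param profile a [CnvProfile-class].
#' @param minSegment minimum windows per segment (default 5).
#' @param penalty cost per breakpoint; NULL for the default.
#' @return The profile with its `segments` slot filled:
#'   [GenomicRanges::GRanges] with `meanLog2` and `nWindows`.
#' @export
segmentProfile <- function(profile, minSegment = 5L, penalty = NULL) {
  stopifnot(is(profile, "CnvProfile"))
  tiles <- profile@windows
  segGR <- GRanges()
  for (ctg in unique(as.character(seqnames(tiles)))) {
    sel <- as.character(seqnames(tiles)) == ctg
    x <- tiles$log2Ratio[sel]
    st <- start(tiles)[sel]; en <- end(tiles)[sel]
    if (length(x) < minSegment) {
      m <- matrix(c(1L, length(x)), nrow = 1)
    } else {
      pen <- penalty
      if (is.null(pen)) {
        sigma2 <- (mad(diff(x)) / sqrt(2))^2
        pen <- 2 * sigma2 * log(length(x))
      }
      m <- .segmentVector(x, minSegment, pen)
    }
    gr <- GRanges(ctg, IRanges(st[m[, 1]], en[m[, 2]]))
    gr$meanLog2 <- vapply(seq_len(nrow(m)), function(i)
      mean(x[m[i, 1]:m[i, 2]]), numeric(1))
    gr$nWindows <- m[, 2] - m[, 1] + 1L
    suppressWarnings(segGR <- c(segGR, gr))
  }
  new("CnvProfile", window = profile@window, windows = tiles,
      segments = segGR)
}
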
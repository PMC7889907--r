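#' @include AllClasses.R utils.R
NULL

#' Build a canonical k-mer seed index
#'
#' Indexes every k-mer of the reference via its canonical form (the
#' lexicographically smaller of the k-mer and its reverse complement), so one
#' lookup serves both strands.  Positions containing N are excluded, and
#' k-mers occurring more than `maxOcc` times (telomere repeats, other
#' high-copy sequence) are dropped from the index: reads drawn from such
#' sequence are inherently ambiguous and would be discarded by the unique-best
#' rule anyway.
#'
#' @param reference [Biostrings::DNAStringSet] (or named character vector).
#' @param k k-mer size, at least 8 (default 15).
#' @param maxOcc occurrence cap per k-mer (default 64).
#' @return A [SeedIndex-class].
#' @export
buildSeedIndex <- function(reference, k = 15L, maxOcc = 64L) {
  if (k < 8L) stop("k must be >= 8")
  if (is(reference, "XStringSet")) {
    seqs <- as.character(reference)
  } else {
    seqs <- reference
  }
  if (is.null(names(seqs)))
    names(seqs) <- sprintf("contig%d", seq_along(seqs))
  if (all(nchar(seqs) < k))
    stop("k is larger than every contig")
  ptr <- .buildIndexCpp(seqs, as.integer(k), as.integer(maxOcc))
  st <- .indexStatsCpp(ptr)
  new("SeedIndex", ptr = ptr, k = as.integer(k), maxOcc = as.integer(maxOcc),
      seqnames = names(seqs),
      seqlengths = setNames(as.integer(nchar(seqs)), names(seqs)),
      mappableLength = st$mappable - sum(nchar(seqs) == 0),
      nKmers = st$nKmers, nPositions = st$nPositions)
}

#' Map reads with a unique-best seed-and-extend aligner
#'
#' Seeds each read with its non-overlapping k-mers (plus the terminal k-mer),
#' turns index hits on either strand into candidate ungapped placements, and
#' scores every candidate over the full read length (score = matches -
#' mismatches).  A read is reported only when its best-scoring placement has
#' at most `maxMismatchFrac * length` mismatches, and -- under
#' `tieBreak = "unique"` -- when that best score is achieved at exactly one
#' locus; ties discard the read.  `tieBreak = "random"` instead resolves ties
#' uniformly at random from R's RNG stream, the behaviour wanted for unbiased
#' depth estimation.
#'
#' @param index a [SeedIndex-class].
#' @param seqs reads (character vector or [Biostrings::DNAStringSet]); names
#'   become read ids.
#' @param maxMismatchFrac maximum mismatch fraction (default 0.05).
#' @param tieBreak `"unique"` (anchor evidence) or `"random"` (depth).
#' @return [GenomicRanges::GRanges] of placements (unmapped reads are absent)
#'   with metadata columns `readId`, `mismatches`, `score`; seqlengths are set
#'   from the index.
#' @export
mapReads <- function(index, seqs, maxMismatchFrac = 0.05,
                     tieBreak = c("unique", "random")) {
  stopifnot(is(index, "SeedIndex"))
  tieBreak <- match.arg(tieBreak)
  ids <- names(seqs)
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  res <- .mapReadsCpp(index@ptr, unname(seqs), maxMismatchFrac,
                      tieBreak == "unique")
  hit <- !is.na(res$contig)
  lens <- nchar(seqs)[hit]
  gr <- GRanges(index@seqnames[res$contig[hit]],
                IRanges(start = res$start[hit] + 1L,
                        width = lens),
                strand = ifelse(res$strand[hit] > 0, "+", "-"),
                readId = ids[hit],
                mismatches = res$mismatches[hit],
                score = lens - 2L * res$mismatches[hit],
                seqlengths = index@seqlengths)
  gr
}

#' Call anchor-enriched candidate template regions
#'
#' Tiles the reference into windows and tests each window's anchor count
#' against a Poisson null with mean `N * w / L_mappable` (N anchors scattered
#' uniformly over the mappable genome), Bonferroni-corrected across windows.
#' Significant windows closer than `maxGap` are merged into one region:
#' telomere-adjacent evidence flanks both ends of a template element, so the
#' gap tolerance (default 10 kb, the scale of one element) joins the two
#' flanks of a locus into a single candidate.
#'
#' @param hits anchor [GenomicRanges::GRanges] from [mapReads()].
#' @param index the [SeedIndex-class] used for mapping (provides window
#'   tiling and the mappable length).
#' @param window window size in bases (default 1000).
#' @param alpha family-wise error target (default 0.01).
#' @param maxGap merge distance for significant windows (default 10000).
#' @return [GenomicRanges::GRanges] of regions, sorted by decreasing
#'   `anchorCount`, with `pAdjMin` (smallest Bonferroni-adjusted window p in
#'   the region) and `nWindows`.
#' @export
collectCandidateRegions <- function(hits, index, window = 1000L, alpha = 0.01,
                                    maxGap = 10000L) {
  if (window <= 0L) stop("window must be positive")
  sl <- index@seqlengths
  tiles <- tileGenome(sl, tilewidth = window, cut.last.tile.in.chrom = TRUE)
  if (length(hits) == 0L)
    return(GRanges(anchorCount = integer(0), pAdjMin = numeric(0),
                   nWindows = integer(0)))
  mids <- resize(hits, width = 1L, fix = "center")
  counts <- countOverlaps(tiles, mids)
  lambda <- length(hits) * width(tiles) / index@mappableLength
  p <- ppois(counts - 1L, lambda, lower.tail = FALSE)
  nW <- length(tiles)
  sig <- p < alpha / nW
  if (!any(sig))
    return(GRanges(anchorCount = integer(0), pAdjMin = numeric(0),
                   nWindows = integer(0)))
  regions <- reduce(tiles[sig], min.gapwidth = maxGap + 1L)
  regions$anchorCount <- countOverlaps(regions, mids)
  ov <- findOverlaps(tiles[sig], regions)
  pAdj <- pmin(p[sig] * nW, 1)
  regions$pAdjMin <- vapply(seq_along(regions), function(i)
    min(pAdj[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == i]]),
    numeric(1))
  regions$nWindows <- vapply(seq_along(regions), function(i)
    sum(S4Vectors::subjectHits(ov) == i), integer(1))
  regions[order(regions$anchorCount, decreasing = TRUE)]
}

#' Call template orientation from strand-typed anchors
#'
#' For each region, considers anchors lying within `endMargin` of the
#' region's 5' or 3' boundary (reference forward-strand coordinate order)
#' whose telomeric partner is G- or C-typed.  Because telomere repeats read
#' TTAGGG on the forward strand, a telomeric mate upstream (left) of its
#' anchored partner is G-typed and one downstream is C-typed; a template
#' inserted in forward orientation therefore accumulates G-partner anchors at
#' its 5' end and C-partner anchors at its 3' end.  The call is FORWARD when
#' at least `tau` of G-partner anchors sit at the 5' end AND at least `tau`
#' of C-partner anchors at the 3' end; REVERSE with ends swapped; NOCALL when
#' informative anchors number fewer than `minInformative`; INCONSISTENT
#' otherwise.
#'
#' @param regions [GenomicRanges::GRanges] regions (e.g. from
#'   [collectCandidateRegions()]).
#' @param hits anchor [GenomicRanges::GRanges] carrying a `partnerType`
#'   metadata column (G/C/AMBIGUOUS); AMBIGUOUS partners are not informative.
#' @param endMargin boundary margin in bases (default 1000).
#' @param tau required proportion (default 0.9).
#' @param minInformative minimum informative anchors (default 20).
#' @return [S4Vectors::DataFrame] with one row per region: orientation, g5,
#'   g3, c5, c3, informative.
#' @export
callOrientation <- function(regions, hits, endMargin = 1000L, tau = 0.9,
                            minInformative = 20L) {
  if (is.null(hits$partnerType))
    stop("hits must carry a partnerType metadata column")
  info <- hits[hits$partnerType %in% c("G", "C")]
  n <- length(regions)
  oriV <- character(n)
  g5V <- g3V <- c5V <- c3V <- infV <- integer(n)
  mid <- (start(info) + end(info)) / 2
  for (i in seq_len(n)) {
    rs <- start(regions)[i]; re <- end(regions)[i]
    onCtg <- as.character(seqnames(info)) == as.character(seqnames(regions)[i])
    at5 <- onCtg & start(info) >= rs & start(info) <= rs + endMargin - 1L
    at3 <- onCtg & end(info) <= re & end(info) >= re - endMargin + 1L
    both <- at5 & at3
    if (any(both)) {
      nearer5 <- (mid - rs) <= (re - mid)
      at5[both] <- nearer5[both]
      at3[both] <- !nearer5[both]
    }
    isG <- info$partnerType == "G"
    g5 <- sum(at5 & isG); g3 <- sum(at3 & isG)
    c5 <- sum(at5 & !isG); c3 <- sum(at3 & !isG)
    tot <- g5 + g3 + c5 + c3
    orientation <- if (tot < minInformative) {
      "NOCALL"
    } else if ((g5 + g3) > 0L && (c5 + c3) > 0L &&
               g5 / (g5 + g3) >= tau && c3 / (c5 + c3) >= tau) {
      "FORWARD"
    } else if ((g5 + g3) > 0L && (c5 + c3) > 0L &&
               g3 / (g5 + g3) >= tau && c5 / (c5 + c3) >= tau) {
      "REVERSE"
    } else {
      "INCONSISTENT"
    }
    oriV[i] <- orientation
    g5V[i] <- g5; g3V[i] <- g3; c5V[i] <- c5; c3V[i] <- c3
    infV[i] <- tot
  }
  DataFrame(orientation = oriV, g5 = g5V, g3 = g3V, c5 = c5V, c3 = c3V,
            informative = infV)
}
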
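#' @include AllClasses.R utils.R
NULL

#' Count non-overlapping motif occurrences
#'
#' Left-to-right greedy, case-insensitive, exact count of a motif in each
#' sequence; occurrences do not overlap.  This is the primitive behind
#' telomeric read classification: a mate containing the telomere unit (or its
#' complement) at least `threshold` times is telomeric.
#'
#' @param seqs character vector or [Biostrings::DNAStringSet].
#' @param motif single non-empty motif string.
#' @return Integer vector of counts.
#' @examples
#' countMotif("TTAGGGTTAGGGTTAGGG", "TTAGGG")  # 3
#' countMotif("TTAGGGATTAGGG", "TTAGGG")       # 2
#' @export
countMotif <- function(seqs, motif) {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L)
    stop("motif must be a single non-empty string")
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  .countMotifCpp(seqs, motif)
}

#' Type mates by telomere-repeat content
#'
#' A mate is G-type when the G-strand unit (TTAGGG) occurs at least
#' `threshold` times and the C-strand unit fewer; C-type symmetrically;
#' AMBIGUOUS when both reach the threshold; NONE otherwise.
#'
#' @param seqs sequences (character or [Biostrings::DNAStringSet]).
#' @param threshold minimum motif count (default 3).
#' @param unit telomere repeat unit; its reverse complement is the C-strand
#'   motif.
#' @return [S4Vectors::DataFrame] with `gCount`, `cCount`, `mateType`.
#' @export
classifyMates <- function(seqs, threshold = 3L, unit = "TTAGGG") {
  if (threshold < 1L) stop("threshold must be >= 1")
  g <- countMotif(seqs, unit)
  c_ <- countMotif(seqs, .rc(unit))
  type <- rep("NONE", length(g))
  type[g >= threshold & c_ < threshold] <- "G"
  type[c_ >= threshold & g < threshold] <- "C"
  type[g >= threshold & c_ >= threshold] <- "AMBIGUOUS"
  DataFrame(gCount = g, cCount = c_, mateType = type)
}

#' Classify read pairs as Pair/Single/None
#'
#' Applies [classifyMates()] to both mates.  A pair is PAIR when both mates
#' are telomeric, SINGLE when exactly one is (its non-telomeric mate is the
#' anchorable mate, and the telomeric partner's strand type is recorded), and
#' NONE otherwise.
#'
#' @param pairs a [PairedReads-class].
#' @param threshold minimum motif count per mate (default 3).
#' @param unit telomere repeat unit.
#' @return [S4Vectors::DataFrame] with one row per pair: id, g1, c1, type1,
#'   len1, g2, c2, type2, len2, category, anchorableMate (1, 2 or NA),
#'   partnerType (strand type of the telomeric mate of a SINGLE pair).
#' @export
classifyPairs <- function(pairs, threshold = 3L, unit = "TTAGGG") {
  stopifnot(is(pairs, "PairedReads"))
  m1 <- classifyMates(pairs@mate1, threshold, unit)
  m2 <- classifyMates(pairs@mate2, threshold, unit)
  t1 <- m1$mateType != "NONE"
  t2 <- m2$mateType != "NONE"
  category <- ifelse(t1 & t2, "PAIR", ifelse(t1 | t2, "SINGLE", "NONE"))
  anchorableMate <- rep(NA_integer_, length(category))
  anchorableMate[t1 & !t2] <- 2L
  anchorableMate[!t1 & t2] <- 1L
  partnerType <- rep(NA_character_, length(category))
  partnerType[t1 & !t2] <- m1$mateType[t1 & !t2]
  partnerType[!t1 & t2] <- m2$mateType[!t1 & t2]
  DataFrame(id = names(pairs@mate1),
            g1 = m1$gCount, c1 = m1$cCount, type1 = m1$mateType,
            len1 = Biostrings::width(pairs@mate1),
            g2 = m2$gCount, c2 = m2$cCount, type2 = m2$mateType,
            len2 = Biostrings::width(pairs@mate2),
            category = category,
            anchorableMate = anchorableMate,
            partnerType = partnerType)
}

#' Estimate genome-wide telomere content
#'
#' Coverage-normalised telomere length from classified pairs: with telomeric
#' base count `B_tel` (the full length of every G-, C- or AMBIGUOUS-typed
#' mate), total sequenced bases `B_total`, genome size `G` and `E` chromosome
#' ends, the mean depth is `d = B_total / G` and the telomere length per end
#' is `L = B_tel / (d * E)`.
#'
#' @param classification result of [classifyPairs()].
#' @param genomeSize genome size in bases (> 0).
#' @param nEnds number of chromosome ends (> 0).
#' @return A [TelomereContentEstimate-class].
#' @export
estimateTelomereContent <- function(classification, genomeSize, nEnds) {
  if (genomeSize <= 0) stop("genomeSize must be > 0")
  if (nEnds <= 0) stop("nEnds must be > 0")
  if (nrow(classification) == 0L)
    stop("insufficient data: no classified pairs")
  telBases <- sum(classification$len1[classification$type1 != "NONE"]) +
    sum(classification$len2[classification$type2 != "NONE"])
  totalBases <- sum(classification$len1) + sum(classification$len2)
  if (totalBases <= 0) stop("insufficient data: zero total bases")
  meanDepth <- totalBases / genomeSize
  new("TelomereContentEstimate",
      telomericBases = as.numeric(telBases),
      totalBases = as.numeric(totalBases),
      genomeSize = as.numeric(genomeSize),
      nEnds = as.integer(nEnds),
      meanDepth = meanDepth,
      lengthPerEnd = telBases / (meanDepth * nEnds))
}

#' Summarise pair categories
#'
#' @param classification result of [classifyPairs()].
#' @return Named integer vector with PAIR, SINGLE and NONE counts.
#' @export
pairCategoryCounts <- function(classification) {
  counts <- table(factor(classification$category,
                         levels = c("PAIR", "SINGLE", "NONE")))
  setNames(as.integer(counts), names(counts))
}
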
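#' @include AllClasses.R utils.R
NULL

#' Define a restriction enzyme
#'
#' @param name enzyme name.
#' @param pattern recognition pattern over A/C/G/T/N; N matches any base.
#' @param cutOffset cut position in bases from the pattern start (0 =
#'   before the first base).
#' @return An [Enzyme-class].
#' @examples
#' enzyme("AluI", "AGCT", 2)
#' @export
enzyme <- function(name, pattern, cutOffset) {
  obj <- new("Enzyme", name = name, pattern = toupper(pattern),
             cutOffset = as.integer(cutOffset))
  validObject(obj)
  obj
}

#' Built-in restriction enzymes
#'
#' AluI (AG^CT), MboI (^GATC) and HinfI (G^ANTC): the enzymes of a terminal
#' restriction fragment (TRF) assay, none of which cuts the canonical
#' telomere repeat.  All three recognition patterns are palindromic.
#'
#' @param names subset of enzyme names; default all three.
#' @return Named list of [Enzyme-class] objects.
#' @export
restrictionEnzymes <- function(names = c("AluI", "MboI", "HinfI")) {
  all <- list(AluI = enzyme("AluI", "AGCT", 2L),
              MboI = enzyme("MboI", "GATC", 0L),
              HinfI = enzyme("HinfI", "GANTC", 1L))
  unknown <- setdiff(names, names(all))
  if (length(unknown))
    stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  all[names]
}

.isPalindromic <- function(pattern) {
  pattern == .rc(pattern)
}

#' Find restriction cut positions
#'
#' Every occurrence of the recognition pattern (N matching any base, via
#' [Biostrings::matchPattern()] with `fixed = "subject"`) contributes a cut
#' at `occurrence start + cutOffset`.  A single-strand scan suffices for
#' palindromic patterns (all built-ins); non-palindromic patterns trigger an
#' automatic second scan of the reverse strand with the mirrored offset.
#'
#' @param seq a DNA string ([Biostrings::DNAString] or character).
#' @param enz an [Enzyme-class].
#' @return Sorted, deduplicated 0-based cut positions (a cut at position p
#'   falls between bases p and p+1 of the forward strand).
#' @export
findSites <- function(seq, enz) {
  stopifnot(is(enz, "Enzyme"))
  if (is.character(seq)) seq <- DNAString(seq)
  pat <- enz@pattern
  m <- matchPattern(pat, seq, fixed = "subject")
  cuts <- start(m) - 1L + enz@cutOffset
  if (!.isPalindromic(pat)) {
    m2 <- matchPattern(.rc(pat), seq, fixed = "subject")
    cuts <- c(cuts, start(m2) - 1L + (nchar(pat) - enz@cutOffset))
  }
  sort(unique(as.integer(cuts)))
}

#' Digest a sequence in silico
#'
#' Applies a set of enzymes, unions their cut positions and returns the
#' fragment lengths between consecutive cuts (terminal fragments included).
#' Sequences are treated as linear.
#'
#' @param seq a DNA string.
#' @param enzymes list of [Enzyme-class] (default: the three built-ins).
#' @return A [DigestResult-class]; fragment lengths always sum to the input
#'   length.
#' @examples
#' digestSequence(strrep("TTAGGG", 10))  # telomere repeats: one uncut fragment
#' @export
digestSequence <- function(seq, enzymes = restrictionEnzymes()) {
  if (is(enzymes, "Enzyme")) enzymes <- list(enzymes)
  if (is.character(seq)) seq <- DNAString(seq)
  L <- length(seq)
  cuts <- sort(unique(unlist(lapply(enzymes, function(e) findSites(seq, e)))))
  cuts <- cuts[cuts > 0L & cuts < L]
  frags <- diff(c(0, cuts, L))
  new("DigestResult",
      enzymes = vapply(enzymes, function(e) e@name, character(1)),
      cuts = as.numeric(cuts), fragments = as.numeric(frags),
      seqLength = as.numeric(L))
}
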
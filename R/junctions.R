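#' @include AllClasses.R utils.R
NULL

# Classify one read on one strand against the probe set.  Returns
# list(class, spacer) or NULL.  Exact matching throughout: the probes act
# like PCR primers -- specificity over sensitivity.
.scanOneStrand <- function(s, headP, tailP, rcHead, rcTail, unit, rcUnit,
                           maxSpacerUnits) {
  probeLen <- nchar(headP)
  unitLen <- nchar(unit)
  countUnits <- function(pos, u) {
    n <- 0L
    while (n < maxSpacerUnits &&
           substr(s, pos, pos + unitLen - 1L) == u) {
      pos <- pos + unitLen
      n <- n + 1L
    }
    list(n = n, pos = pos)
  }
  # TAIL ... -> HEAD_TO_TAIL or TAIL_TO_TAIL
  m <- gregexpr(tailP, s, fixed = TRUE)[[1]]
  if (m[1] != -1L) {
    for (p in as.integer(m)) {
      u <- countUnits(p + probeLen, unit)
      after <- substr(s, u$pos, u$pos + probeLen - 1L)
      if (after == headP) return(list(class = "HEAD_TO_TAIL", spacer = u$n))
      if (after == rcTail) return(list(class = "TAIL_TO_TAIL", spacer = u$n))
    }
  }
  # rc(HEAD) ... HEAD -> HEAD_TO_HEAD; the strand flips at the junction, so
  # spacer units may read as either the unit or its complement
  m <- gregexpr(rcHead, s, fixed = TRUE)[[1]]
  if (m[1] != -1L) {
    for (p in as.integer(m)) {
      for (u0 in c(unit, rcUnit)) {
        u <- countUnits(p + probeLen, u0)
        after <- substr(s, u$pos, u$pos + probeLen - 1L)
        if (after == headP) return(list(class = "HEAD_TO_HEAD", spacer = u$n))
      }
    }
  }
  NULL
}

#' Type template-template junctions from single reads
#'
#' The in-silico analogue of a directional junction PCR: HEAD is the first
#' `probeLen` bases of the template and TAIL the last `probeLen`.  A read (or
#' its reverse complement) containing TAIL, then 0 to `maxSpacerUnits`
#' complete telomere units, then HEAD is a HEAD_TO_TAIL junction; TAIL
#' followed by reverse-complemented TAIL is TAIL_TO_TAIL; reverse-complemented
#' HEAD followed by HEAD is HEAD_TO_HEAD.  Matching is exact: at typical
#' substitution error rates most junction reads still match, and specificity
#' is the point.
#'
#' @param seqs reads (character or [Biostrings::DNAStringSet]).
#' @param template template element sequence (single string or
#'   [Biostrings::DNAString]).
#' @param probeLen probe length in bases (default 30).
#' @param unit telomere repeat unit.
#' @param maxSpacerUnits maximum telomere units between the probes.
#' @return [S4Vectors::DataFrame] with `readId`, `junctionClass` (one of
#'   HEAD_TO_TAIL, HEAD_TO_HEAD, TAIL_TO_TAIL, UNCLASSIFIED) and
#'   `spacerUnits` (NA when unclassified).
#' @export
scanJunctionReads <- function(seqs, template, probeLen = 30L, unit = "TTAGGG",
                              maxSpacerUnits = 30L) {
  template <- as.character(template)
  if (nchar(template) < 2L * probeLen)
    stop("probeLen too large: template must be at least twice the probe length")
  ids <- names(seqs)
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  headP <- substr(template, 1L, probeLen)
  tailP <- substr(template, nchar(template) - probeLen + 1L, nchar(template))
  rcHead <- .rc(headP)
  rcTail <- .rc(tailP)
  rcUnit <- .rc(unit)
  hasT <- grepl(tailP, seqs, fixed = TRUE)
  hasH <- grepl(headP, seqs, fixed = TRUE)
  hasRT <- grepl(rcTail, seqs, fixed = TRUE)
  hasRH <- grepl(rcHead, seqs, fixed = TRUE)
  cand <- which((hasT & hasH) | (hasRH & hasRT) | (hasT & hasRT) |
                  (hasRH & hasH))
  cls <- rep("UNCLASSIFIED", length(seqs))
  spc <- rep(NA_integer_, length(seqs))
  for (i in cand) {
    r <- .scanOneStrand(seqs[i], headP, tailP, rcHead, rcTail, unit, rcUnit,
                        maxSpacerUnits)
    if (is.null(r))
      r <- .scanOneStrand(.rc(seqs[i]), headP, tailP, rcHead, rcTail, unit,
                          rcUnit, maxSpacerUnits)
    if (!is.null(r)) {
      cls[i] <- r$class
      spc[i] <- r$spacer
    }
  }
  DataFrame(readId = ids, junctionClass = cls, spacerUnits = spc)
}

#' Summarise junction calls
#'
#' Counts calls per junction class, reports the dominant class (a class is
#' dominant when it holds at least `dominance` of the classified calls and at
#' least 10 reads were classified) and tabulates observed spacer units.
#'
#' @param calls result of [scanJunctionReads()].
#' @param dominance dominance threshold on the classified share (default 0.8).
#' @return A list: `counts` (named, all four classes), `nClassified`,
#'   `dominantClass` (class name or NA), `modalSpacer` (NA when nothing
#'   classified), `spacerHistogram` (table).
#' @export
summarizeJunctions <- function(calls, dominance = 0.8) {
  lev <- c("HEAD_TO_TAIL", "HEAD_TO_HEAD", "TAIL_TO_TAIL", "UNCLASSIFIED")
  counts <- table(factor(calls$junctionClass, levels = lev))
  classified <- counts[setdiff(lev, "UNCLASSIFIED")]
  nClassified <- sum(classified)
  dominant <- NA_character_
  if (nClassified >= 10L) {
    top <- which.max(classified)
    if (classified[top] / nClassified >= dominance)
      dominant <- names(classified)[top]
  }
  spacers <- calls$spacerUnits[!is.na(calls$spacerUnits)]
  hist <- table(spacers)
  modal <- if (length(hist)) as.integer(names(hist)[which.max(hist)]) else NA_integer_
  list(counts = setNames(as.integer(counts), names(counts)),
       nClassified = as.integer(nClassified),
       dominantClass = dominant,
       modalSpacer = modal,
       spacerHistogram = hist)
}
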
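#' @include AllClasses.R utils.R
NULL

#' Create a simulation configuration
#'
#' Builds a validated [SimConfig-class].  The defaults describe the study
#' conditions the package is designed around: a small diploid genome whose
#' chromosome ends are canonical telomere arrays before ALT activation and,
#' afterwards, tandem head-to-tail arrays of a 7,370 bp template element
#' separated by 8-unit telomere-repeat spacers, with two paralogous template
#' loci (interstitial "A", subterminal "B") distinguished by marker SNPs and
#' exactly one of them amplified.
#'
#' @param seed integer seed; all randomness of a simulation derives from it.
#' @param nChromosomes,chromLength genome shape (diploid; two haplotypes per
#'   chromosome, homozygous architecture).
#' @param templateLength,paralogMarkerCount template element parameters.
#' @param telomereUnit canonical telomere repeat (G-strand).
#' @param preAltTelomereLength telomere bases per end before ALT.
#' @param altCopiesPerEnd,spacerUnits,terminalTelomereUnits post-ALT array
#'   architecture: copies per rebuilt (q-arm) end, telomere units between
#'   copies, and the short terminal tract after the last copy.
#' @param selectedParalog which paralog seeds the arrays ("A" or "B").
#' @param templateOrientation "forward" or "reverse" insertion.
#' @param readLength,fragmentMean,fragmentSd,coverage,substitutionErrorRate
#'   read simulator parameters.
#' @param markerMargin marker-free template bases at each template end.
#' @return A [SimConfig-class].
#' @examples
#' cfg <- simConfig(seed = 1, chromLength = 60000L, templateLength = 2000L,
#'                  preAltTelomereLength = 1500L, readLength = 100L,
#'                  fragmentMean = 300, fragmentSd = 30)
#' cfg
#' @export
simConfig <- function(seed = 1L,
                      nChromosomes = 2L,
                      chromLength = 500000L,
                      templateLength = 7370L,
                      paralogMarkerCount = 10L,
                      telomereUnit = "TTAGGG",
                      preAltTelomereLength = 5000L,
                      altCopiesPerEnd = 8L,
                      spacerUnits = 8L,
                      terminalTelomereUnits = 10L,
                      selectedParalog = "B",
                      templateOrientation = "forward",
                      readLength = 150L,
                      fragmentMean = 450,
                      fragmentSd = 50,
                      coverage = 30,
                      substitutionErrorRate = 0.002,
                      markerMargin = 200L) {
  obj <- new("SimConfig",
             seed = as.integer(seed),
             nChromosomes = as.integer(nChromosomes),
             chromLength = as.integer(chromLength),
             templateLength = as.integer(templateLength),
             paralogMarkerCount = as.integer(paralogMarkerCount),
             telomereUnit = toupper(telomereUnit),
             preAltTelomereLength = as.integer(preAltTelomereLength),
             altCopiesPerEnd = as.integer(altCopiesPerEnd),
             spacerUnits = as.integer(spacerUnits),
             terminalTelomereUnits = as.integer(terminalTelomereUnits),
             selectedParalog = selectedParalog,
             templateOrientation = templateOrientation,
             readLength = as.integer(readLength),
             fragmentMean = as.numeric(fragmentMean),
             fragmentSd = as.numeric(fragmentSd),
             coverage = as.numeric(coverage),
             substitutionErrorRate = as.numeric(substitutionErrorRate),
             markerMargin = as.integer(markerMargin))
  v <- validObject(obj, test = TRUE)
  if (!isTRUE(v)) .stopConfig(paste(v, collapse = "; "))
  obj
}

# Deterministic architectural core shared by the pre- and post-ALT builders:
# template sequence, paralog marker table and per-chromosome body sequences.
# Drawing everything here (in a fixed order, from one derived seed) guarantees
# that the two phases describe the same genome lineage.
.simCore <- function(cfg) {
  set.seed(.derivedSeed(cfg@seed, "architecture"))
  tl <- cfg@templateLength
  template <- .randomDNA(tl)
  nm <- cfg@paralogMarkerCount
  if (nm > 0L) {
    pos <- unique(round(seq(cfg@markerMargin + 1L, tl - cfg@markerMargin,
                            length.out = nm)))
    alleleA <- vapply(pos, function(p) substr(template, p, p), character(1))
    alleleB <- vapply(alleleA, function(a)
      sample(setdiff(c("A", "C", "G", "T"), a), 1L), character(1),
      USE.NAMES = FALSE)
  } else {
    pos <- integer(0); alleleA <- character(0); alleleB <- character(0)
  }
  templateA <- template
  templateB <- template
  for (i in seq_along(pos)) substr(templateB, pos[i], pos[i]) <- alleleB[i]
  telLen <- cfg@preAltTelomereLength
  unitLen <- nchar(cfg@telomereUnit)
  spacerBases <- cfg@spacerUnits * unitLen
  avail1 <- cfg@chromLength - 2L * telLen - tl
  b1 <- max(1000L, as.integer(floor(avail1 * 0.45)))
  b2 <- avail1 - b1
  bodies <- vector("list", cfg@nChromosomes)
  bodies[[1]] <- list(body1 = .randomDNA(b1), body2 = .randomDNA(b2))
  if (cfg@nChromosomes >= 2L) {
    avail2 <- cfg@chromLength - 2L * telLen - tl - spacerBases
    bodies[[2]] <- list(body = .randomDNA(avail2))
  }
  if (cfg@nChromosomes > 2L) {
    for (i in 3:cfg@nChromosomes)
      bodies[[i]] <- list(body = .randomDNA(cfg@chromLength - 2L * telLen))
  }
  list(template = template, templateA = templateA, templateB = templateB,
       markerPos = pos, alleleA = alleleA, alleleB = alleleB,
       bodies = bodies, b1 = b1, b2 = b2)
}

# One chromosome as an ordered piece list: each piece is
# list(label, strand, seq).  Forward-strand convention: the left (p-arm)
# telomere reads CCCTAA and the right (q-arm) telomere reads TTAGGG.
.chromPieces <- function(i, core, cfg, phase) {
  unit <- cfg@telomereUnit
  telLen <- cfg@preAltTelomereLength
  leftTel <- list(label = "telomere_repeat", strand = "*",
                  seq = .rc(.repeatTract(unit, telLen)))
  rightTel <- list(label = "telomere_repeat", strand = "*",
                   seq = .repeatTract(unit, telLen))
  spacer <- list(label = "spacer", strand = "*",
                 seq = strrep(unit, cfg@spacerUnits))
  tmplSel <- if (cfg@selectedParalog == "A") core$templateA else core$templateB
  selLabel <- paste0("template_", cfg@selectedParalog)
  fwd <- cfg@templateOrientation == "forward"
  arrayPiece <- list(label = selLabel, strand = if (fwd) "+" else "-",
                     seq = if (fwd) tmplSel else .rc(tmplSel))
  altArray <- c(rep(list(spacer, arrayPiece), cfg@altCopiesPerEnd),
                list(list(label = "telomere_repeat", strand = "*",
                          seq = strrep(unit, cfg@terminalTelomereUnits))))
  interior <- if (i == 1L) {
    list(list(label = "subtelomere", strand = "*", seq = core$bodies[[1]]$body1),
         list(label = "template_A", strand = "+", seq = core$templateA),
         list(label = "subtelomere", strand = "*", seq = core$bodies[[1]]$body2))
  } else if (i == 2L) {
    list(list(label = "subtelomere", strand = "*", seq = core$bodies[[2]]$body))
  } else {
    list(list(label = "subtelomere", strand = "*", seq = core$bodies[[i]]$body))
  }
  if (phase == "preALT") {
    tailPieces <- if (i == 2L)
      list(spacer,
           list(label = "template_B", strand = "+", seq = core$templateB),
           rightTel)
    else list(rightTel)
  } else {
    tailPieces <- altArray
  }
  c(list(leftTel), interior, tailPieces)
}

# Mapping-reference pieces: one template copy only (paralog A's interstitial
# locus); the subterminal paralog-B locus is absent, as it would be from a
# standard reference assembly.
.refPieces <- function(i, core, cfg) {
  pieces <- .chromPieces(i, core, cfg, "preALT")
  if (i == 2L)
    pieces <- Filter(function(p) !p$label %in% c("spacer", "template_B"),
                     pieces)
  pieces
}

.assemble <- function(pieces) {
  seqs <- vapply(pieces, `[[`, character(1), "seq")
  w <- nchar(seqs)
  keep <- w > 0L
  seqs <- seqs[keep]; w <- w[keep]
  pieces <- pieces[keep]
  ends <- cumsum(w)
  starts <- ends - w + 1L
  list(seq = paste(seqs, collapse = ""),
       segments = data.frame(
         start = starts, end = ends,
         label = vapply(pieces, `[[`, character(1), "label"),
         strand = vapply(pieces, `[[`, character(1), "strand"),
         stringsAsFactors = FALSE))
}

# Telomere-repeat bases belonging to one chromosome end: walk segments inward
# from the end, summing telomere_repeat and spacer widths; template copies
# embedded in the terminal array are passed over; the first subtelomere
# segment terminates the walk.
.endTelomereBases <- function(segdf, fromLeft) {
  ord <- if (fromLeft) seq_len(nrow(segdf)) else rev(seq_len(nrow(segdf)))
  total <- 0
  for (j in ord) {
    lab <- segdf$label[j]
    if (lab %in% c("telomere_repeat", "spacer")) {
      total <- total + (segdf$end[j] - segdf$start[j] + 1L)
    } else if (lab == "subtelomere") {
      break
    }
  }
  total
}

.buildGenome <- function(cfg, phase) {
  core <- .simCore(cfg)
  nChr <- cfg@nChromosomes
  genomeSeqs <- character(0)
  segAll <- NULL
  refSeqs <- character(nChr)
  telEnds <- numeric(0)
  for (i in seq_len(nChr)) {
    asm <- .assemble(.chromPieces(i, core, cfg, phase))
    for (h in 1:2) {
      ctg <- sprintf("chr%d_h%d", i, h)
      genomeSeqs[ctg] <- asm$seq
      sd <- asm$segments
      sd$contig <- ctg
      segAll <- rbind(segAll, sd)
      telEnds[paste0(ctg, ":L")] <- .endTelomereBases(asm$segments, TRUE)
      telEnds[paste0(ctg, ":R")] <- .endTelomereBases(asm$segments, FALSE)
    }
    refSeqs[i] <- .assemble(.refPieces(i, core, cfg))$seq
  }
  names(refSeqs) <- sprintf("chr%d", seq_len(nChr))
  genome <- DNAStringSet(genomeSeqs)
  reference <- DNAStringSet(refSeqs)
  segments <- GRanges(segAll$contig,
                      IRanges(segAll$start, segAll$end),
                      strand = segAll$strand,
                      label = segAll$label,
                      seqlengths = setNames(nchar(genomeSeqs),
                                            names(genomeSeqs)))
  nTemplate <- sum(grepl("^template_", segments$label))
  telLen <- cfg@preAltTelomereLength
  aStart <- telLen + core$b1 + 1L
  templateRegion <- GRanges("chr1",
                            IRanges(aStart, aStart + cfg@templateLength - 1L))
  ctlStart <- aStart + cfg@templateLength + 1000L
  controlRegion <- GRanges("chr1",
                           IRanges(ctlStart, ctlStart + cfg@templateLength - 1L))
  markers <- data.frame(
    templatePos = core$markerPos,
    alleleA = core$alleleA,
    alleleB = core$alleleB,
    refContig = rep("chr1", length(core$markerPos)),
    refPos = aStart + core$markerPos - 1L,
    stringsAsFactors = FALSE)
  expectedOrientation <- if (phase == "postALT") {
    if (cfg@templateOrientation == "forward") "FORWARD" else "REVERSE"
  } else "NONE"
  truth <- new("SimTruth",
               segments = segments,
               copyNumber = nTemplate / 2,
               selectedParalog = cfg@selectedParalog,
               markers = markers,
               expectedJunction = if (phase == "postALT") "HEAD_TO_TAIL" else "NONE",
               expectedOrientation = expectedOrientation,
               telomereBasesPerEnd = telEnds,
               templateRegion = templateRegion,
               controlRegion = controlRegion,
               genomeSize = sum(nchar(genomeSeqs)),
               nEnds = 2L * length(genomeSeqs),
               phase = phase)
  validObject(truth)
  new("AltSimulation", config = cfg, phase = phase, genome = genome,
      reference = reference, truth = truth)
}

#' Build a pre-ALT diploid toy genome
#'
#' Chromosome ends carry canonical telomere-repeat arrays.  Each haploid
#' genome contains exactly two template copies: paralog A interstitially on
#' chromosome 1 and paralog B subterminally on chromosome 2, joined to the
#' subtelomere by `spacerUnits` telomere units and followed by the terminal
#' telomere.  Both haplotypes of a chromosome are identical (the homozygous
#' architecture observed for the subterminal template locus).
#'
#' @param config a [SimConfig-class], see [simConfig()].
#' @return An [AltSimulation-class] bundling the diploid genome, the haploid
#'   mapping reference (single template copy) and the [SimTruth-class].
#' @seealso [buildAltGenome()], [simulateReads()]
#' @examples
#' sim <- buildPreAltGenome(simConfig(seed = 1, chromLength = 60000L,
#'   templateLength = 2000L, preAltTelomereLength = 1500L, readLength = 100L,
#'   fragmentMean = 300, fragmentSd = 30))
#' simTruth(sim)@copyNumber   # 2 per haploid genome
#' @export
buildPreAltGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  .buildGenome(config, "preALT")
}

#' Build a post-ALT diploid toy genome
#'
#' The q-arm end of every chromosome is rebuilt as `altCopiesPerEnd` tandem
#' copies of the selected paralog in uniform orientation, each copy preceded
#' by `spacerUnits` telomere units and the array terminated by a short
#' terminal telomere tract.  The interstitial paralog-A locus is retained, so
#' the truth copy number per haploid genome is
#' `1 + nChromosomes * altCopiesPerEnd`.
#'
#' @inheritParams buildPreAltGenome
#' @return An [AltSimulation-class]; `simTruth(x)@expectedJunction` is
#'   `"HEAD_TO_TAIL"`.
#' @export
buildAltGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  .buildGenome(config, "postALT")
}

#' Simulate paired-end reads
#'
#' Draws `round(totalBases * coverage / (2 * readLength))` fragments with
#' uniform start positions and Normal(fragmentMean, fragmentSd) lengths
#' (truncated at twice the read length and at the contig length), reports the
#' two fragment ends as a forward read and the reverse complement of the
#' fragment end, applies independent per-base substitutions at
#' `substitutionErrorRate`, and assigns a constant Q30 quality.  Which
#' physical mate becomes mate 1 is random, as in real libraries.
#'
#' @param sim an [AltSimulation-class] (reads are drawn from its haplotype
#'   contigs) or a [Biostrings::DNAStringSet].
#' @param config a [SimConfig-class]; defaults to `sim@config` when `sim` is
#'   an [AltSimulation-class].
#' @param stream label naming the RNG stream (distinct labels give independent
#'   read sets from one seed); defaults to `"reads_<phase>"`.
#' @return A [PairedReads-class].
#' @export
simulateReads <- function(sim, config = NULL, stream = NULL) {
  if (is(sim, "AltSimulation")) {
    genome <- sim@genome
    if (is.null(config)) config <- sim@config
    if (is.null(stream)) stream <- paste0("reads_", sim@phase)
  } else {
    genome <- sim
    if (is.null(config)) .stopConfig("config is required for a raw genome")
    if (is.null(stream)) stream <- "reads"
  }
  if (length(genome) == 0L) .stopConfig("genome is empty")
  set.seed(.derivedSeed(config@seed, stream))
  rl <- config@readLength
  w <- Biostrings::width(genome)
  totalBases <- sum(as.numeric(w))
  nPairs <- round(totalBases * config@coverage / (2 * rl))
  ci <- sample.int(length(genome), nPairs, replace = TRUE, prob = w)
  fragLen <- pmax(2L * rl, as.integer(round(rnorm(nPairs, config@fragmentMean,
                                                  config@fragmentSd))))
  fragLen <- pmin(fragLen, w[ci])
  startPos <- 1L + as.integer(floor(runif(nPairs) * (w[ci] - fragLen + 1)))
  flip <- runif(nPairs) < 0.5
  seqChar <- as.character(genome)
  fwd <- character(nPairs)
  revRaw <- character(nPairs)
  for (k in seq_along(genome)) {
    idx <- which(ci == k)
    if (!length(idx)) next
    s <- startPos[idx]
    e <- s + fragLen[idx] - 1L
    fwd[idx] <- substring(seqChar[k], s, s + rl - 1L)
    revRaw[idx] <- substring(seqChar[k], e - rl + 1L, e)
  }
  rev <- .rc(revRaw)
  if (config@substitutionErrorRate > 0) {
    fwd <- .addSubstitutionsCpp(fwd, config@substitutionErrorRate)
    rev <- .addSubstitutionsCpp(rev, config@substitutionErrorRate)
  }
  m1 <- fwd; m2 <- rev
  m1[flip] <- rev[flip]
  m2[flip] <- fwd[flip]
  ids <- sprintf("sim_%07d", seq_len(nPairs))
  mate1 <- DNAStringSet(m1); names(mate1) <- ids
  mate2 <- DNAStringSet(m2); names(mate2) <- ids
  new("PairedReads", mate1 = mate1, mate2 = mate2, qualityChar = "?")
}
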
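#' @include AllClasses.R
NULL

#' Write paired reads as a FASTQ pair
#'
#' Plain Phred+33 FASTQ with `/1` and `/2` suffixed read ids and the
#' constant-quality model of [PairedReads-class].
#'
#' @param pairs a [PairedReads-class].
#' @param r1,r2 output paths for mate 1 and mate 2.
#' @return Invisibly, `c(r1, r2)`.
#' @export
writeReadsFastq <- function(pairs, r1, r2) {
  stopifnot(is(pairs, "PairedReads"))
  .writeMate <- function(seqs, suffix, path) {
    s <- as.character(seqs)
    q <- strrep(pairs@qualityChar, nchar(s))
    lines <- as.vector(rbind(paste0("@", names(seqs), suffix), s, "+", q))
    writeLines(lines, path)
  }
  .writeMate(pairs@mate1, "/1", r1)
  .writeMate(pairs@mate2, "/2", r2)
  invisible(c(r1, r2))
}

#' Read a FASTQ pair
#'
#' Reads two Phred+33 FASTQ files via [Biostrings::readDNAStringSet()].
#' Trailing `/1`, `/2` mate tags and description text are stripped from ids;
#' qualities are discarded (classification is quality-agnostic).
#'
#' @param r1,r2 FASTQ paths.
#' @return A [PairedReads-class].
#' @export
readPairedFastq <- function(r1, r2) {
  .readMate <- function(path) {
    x <- readDNAStringSet(path, format = "fastq")
    names(x) <- sub("/[12]$", "", sub("[ \t].*$", "", names(x)))
    x
  }
  m1 <- .readMate(r1)
  m2 <- .readMate(r2)
  if (!identical(names(m1), names(m2)))
    .stopData("mate ids of the two FASTQ files do not match")
  new("PairedReads", mate1 = m1, mate2 = m2, qualityChar = "?")
}

#' Write a simulated genome and its truth
#'
#' Writes the haplotype genome and mapping reference as 60-column FASTA, the
#' truth segment tiling as BED (0-based half-open) and the full truth record
#' as JSON.
#'
#' @param sim an [AltSimulation-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of paths written.
#' @export
writeSimulation <- function(sim, dir) {
  stopifnot(is(sim, "AltSimulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             reference = file.path(dir, "reference.fasta"),
             truth_bed = file.path(dir, "truth_segments.bed"),
             truth_json = file.path(dir, "truth.json"))
  writeXStringSet(sim@genome, paths["genome"], width = 60L)
  writeXStringSet(sim@reference, paths["reference"], width = 60L)
  seg <- sim@truth@segments
  names(seg) <- seg$label
  rtracklayer::export(seg, paths["truth_bed"], format = "BED")
  tr <- sim@truth
  jsonlite::write_json(list(
    phase = tr@phase,
    copyNumber = tr@copyNumber,
    selectedParalog = tr@selectedParalog,
    expectedJunction = tr@expectedJunction,
    expectedOrientation = tr@expectedOrientation,
    genomeSize = tr@genomeSize,
    nEnds = tr@nEnds,
    telomereBasesPerEnd = as.list(tr@telomereBasesPerEnd),
    templateRegion = sprintf("%s:%d-%d", as.character(seqnames(tr@templateRegion)),
                             start(tr@templateRegion), end(tr@templateRegion)),
    controlRegion = sprintf("%s:%d-%d", as.character(seqnames(tr@controlRegion)),
                            start(tr@controlRegion), end(tr@controlRegion)),
    markers = tr@markers,
    segments = data.frame(contig = as.character(seqnames(seg)),
                          start = start(seg), end = end(seg),
                          label = seg$label,
                          strand = as.character(strand(seg)))),
    paths["truth_json"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Write a data.frame as TSV with a '#'-prefixed header line.
.writeTsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(colnames(df), collapse = "\t")), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
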
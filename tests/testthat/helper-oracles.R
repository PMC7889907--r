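# Brute-force sliding-window oracle for non-overlapping greedy motif counts.
oracleCount <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  i <- 1L; cnt <- 0L
  while (i + m - 1L <= n) {
    if (substr(seq, i, i + m - 1L) == motif) {
      cnt <- cnt + 1L
      i <- i + m
    } else {
      i <- i + 1L
    }
  }
  cnt
}

# Exhaustive best-placement oracle: scans every offset on both strands of
# every contig, scoring matches - mismatches over the full read; returns the
# best placement only when unique and within the mismatch cap.
oracleMap <- function(read, contigs, maxMismatchFrac = 0.05) {
  len <- nchar(read)
  cap <- floor(maxMismatchFrac * len)
  rq <- utf8ToInt(read)
  best <- NULL; bestMm <- len + 1L; nBest <- 0L
  for (ctg in names(contigs)) {
    s <- contigs[[ctg]]
    for (strand in c("+", "-")) {
      q <- if (strand == "+") rq else utf8ToInt(rcChar(read))
      L <- nchar(s)
      if (L < len) next
      w <- utf8ToInt(s)
      m <- embed(w, len)[, len:1, drop = FALSE]   # rows: windows
      mm <- rowSums(m != matrix(q, nrow(m), len, byrow = TRUE))
      for (o in which(mm <= bestMm)) {
        if (mm[o] < bestMm) {
          bestMm <- mm[o]; nBest <- 1L
          best <- list(contig = ctg, start = o, strand = strand, mm = mm[o])
        } else if (mm[o] == bestMm) {
          if (!(identical(best$contig, ctg) && best$start == o &&
                  best$strand == strand))
            nBest <- nBest + 1L
        }
      }
    }
  }
  if (is.null(best) || bestMm > cap || nBest > 1L) return(NULL)
  best
}
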
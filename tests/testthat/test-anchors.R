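test_that("index statistics and round-trip verification hold", {
  set.seed(5)
  ctg <- randomSeq(100)
  idx <- buildSeedIndex(c(c1 = ctg), k = 15L)
  expect_equal(idx@nPositions, 100 - 15 + 1)  # L - k + 1 per strand pair
  expect_true(taltkit:::.verifyIndexCpp(idx@ptr))
  # all-N contig: nothing indexed
  idxN <- buildSeedIndex(c(n = strrep("N", 80), c1 = ctg), k = 15L)
  expect_equal(idxN@nPositions, 86)
  expect_equal(idxN@mappableLength, 100)
  expect_error(buildSeedIndex(c(a = "ACGT"), k = 15L), "larger than")
  expect_error(buildSeedIndex(c(c1 = ctg), k = 4L), "k must be")
})

test_that("exact reads and their reverse complements map to the same interval", {
  set.seed(6)
  ctg <- randomSeq(20000)
  idx <- buildSeedIndex(c(c1 = ctg))
  read <- substr(ctg, 10001, 10100)
  h <- mapReads(idx, c(r = read))
  expect_equal(GenomicRanges::start(h), 10001)
  expect_equal(GenomicRanges::end(h), 10100)
  expect_equal(as.character(GenomicRanges::strand(h)), "+")
  expect_equal(h$mismatches, 0L)
  hrc <- mapReads(idx, c(r = rcChar(read)))
  expect_equal(GenomicRanges::start(hrc), 10001)
  expect_equal(as.character(GenomicRanges::strand(hrc)), "-")
})

test_that("reads present at two loci are discarded as ambiguous", {
  set.seed(7)
  u <- randomSeq(300)
  ctg <- paste0(randomSeq(500), u, randomSeq(500), u, randomSeq(500))
  idx <- buildSeedIndex(c(c1 = ctg))
  read <- substr(u, 50, 149)
  expect_equal(length(mapReads(idx, c(r = read), tieBreak = "unique")), 0L)
  # random tie-break places it at one of the two copies
  set.seed(1)
  h <- mapReads(idx, c(r = read), tieBreak = "random")
  expect_equal(length(h), 1L)
  expect_true(GenomicRanges::start(h) %in% c(500 + 50, 500 + 300 + 500 + 50))
})

test_that("mapping agrees with the exhaustive-scan oracle on mutated reads", {
  set.seed(8)
  contigs <- list(cA = randomSeq(2000), cB = randomSeq(2000))
  idx <- buildSeedIndex(unlist(contigs))
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    ctg <- sample(names(contigs), 1)
    len <- sample(c(80L, 100L, 150L), 1)
    o <- sample(2000 - len, 1)
    read <- substr(contigs[[ctg]], o, o + len - 1L)
    nmut <- sample(1:3, 1)
    for (p in sample(len, nmut)) {
      substr(read, p, p) <- sample(setdiff(bases, substr(read, p, p)), 1)
    }
    if (runif(1) < 0.5) read <- rcChar(read)
    got <- mapReads(idx, c(r = read))
    want <- oracleMap(read, contigs)
    if (is.null(want)) {
      expect_equal(length(got), 0L)
    } else {
      expect_equal(length(got), 1L)
      expect_equal(as.character(GenomicRanges::seqnames(got)), want$contig)
      expect_equal(GenomicRanges::start(got), want$start)
      expect_equal(got$mismatches, want$mm)
    }
  }
})

test_that("mapping is symmetric under reverse complement", {
  set.seed(9)
  ctg <- randomSeq(5000)
  idx <- buildSeedIndex(c(c1 = ctg))
  for (i in 1:50) {
    o <- sample(4850, 1)
    read <- substr(ctg, o, o + 119L)
    for (p in sample(120, 2)) {
      substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    h1 <- mapReads(idx, c(r = read))
    h2 <- mapReads(idx, c(r = rcChar(read)))
    expect_equal(length(h1), length(h2))
    if (length(h1)) {
      expect_equal(GenomicRanges::start(h1), GenomicRanges::start(h2))
      expect_true(as.character(GenomicRanges::strand(h1)) !=
                    as.character(GenomicRanges::strand(h2)))
    }
  }
})

test_that("a dense anchor window is called against the Poisson background", {
  # 60 anchors over 500 kb, 50 of them in one window: lambda = 0.12
  idx <- smallIndex()
  sl <- c(chr = 500000L)
  fakeIndex <- new("SeedIndex", ptr = idx@ptr, k = 15L, maxOcc = 64L,
                   seqnames = "chr", seqlengths = sl,
                   mappableLength = 5e5, nKmers = 0, nPositions = 0)
  starts <- c(round(seq(250100, 250900, length.out = 50)),
              round(seq(10000, 490000, length.out = 10)))
  hits <- GenomicRanges::GRanges("chr", IRanges::IRanges(starts, width = 100),
                                 seqlengths = sl)
  regions <- collectCandidateRegions(hits, fakeIndex, window = 1000L,
                                     alpha = 0.01)
  expect_gte(length(regions), 1L)
  expect_true(any(GenomicRanges::start(regions) <= 250100 &
                    GenomicRanges::end(regions) >= 250900))
  expect_equal(length(collectCandidateRegions(hits[0], fakeIndex)), 0L)
})

test_that("uniform null anchors rarely produce any region (Bonferroni guarantee)", {
  idx <- smallIndex()
  sl <- c(chr = 500000L)
  fakeIndex <- new("SeedIndex", ptr = idx@ptr, k = 15L, maxOcc = 64L,
                   seqnames = "chr", seqlengths = sl,
                   mappableLength = 5e5, nKmers = 0, nPositions = 0)
  set.seed(10)
  falsePositives <- 0L
  for (i in 1:100) {
    starts <- sample.int(499900L, 60L)
    hits <- GenomicRanges::GRanges("chr", IRanges::IRanges(starts, width = 100),
                                   seqlengths = sl)
    if (length(collectCandidateRegions(hits, fakeIndex, alpha = 0.01)) > 0L)
      falsePositives <- falsePositives + 1L
  }
  expect_lte(falsePositives, 4L)
})

test_that("orientation calls follow the strand-typed end rule", {
  region <- GenomicRanges::GRanges("chr", IRanges::IRanges(10001, 18000))
  mkHits <- function(nG5, nG3, nC5, nC3) {
    gr <- GenomicRanges::GRanges(
      "chr",
      IRanges::IRanges(c(rep(10050, nG5), rep(17850, nG3),
                         rep(10050, nC5), rep(17850, nC3)), width = 100))
    gr$partnerType <- c(rep("G", nG5 + nG3), rep("C", nC5 + nC3))
    gr
  }
  # G-partners at the 5' end, C-partners at the 3' end: forward insertion
  expect_equal(callOrientation(region, mkHits(30, 0, 0, 25))$orientation,
               "FORWARD")
  expect_equal(callOrientation(region, mkHits(0, 30, 25, 0))$orientation,
               "REVERSE")
  expect_equal(callOrientation(region, mkHits(10, 10, 10, 10))$orientation,
               "INCONSISTENT")
  expect_equal(callOrientation(region, mkHits(3, 0, 0, 2))$orientation,
               "NOCALL")
})

test_that("the top region recovers the template locus with correct orientation", {
  res <- smallPostAnalysis()
  tr <- simTruth(smallPost())
  top <- res$topRegion
  expect_false(is.null(top))
  inter <- GenomicRanges::intersect(top, tr@templateRegion)
  uni <- GenomicRanges::union(top, tr@templateRegion)
  jac <- sum(GenomicRanges::width(inter)) / sum(GenomicRanges::width(uni))
  expect_gte(jac, 0.5)
  expect_equal(top$orientation, tr@expectedOrientation)
})
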
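grFor <- function(ctg, s, e, sl) {
  GenomicRanges::GRanges(ctg, IRanges::IRanges(s, e), seqlengths = sl)
}

test_that("depth tracks conserve aligned bases", {
  sl <- c(c1 = 1000L)
  hits <- grFor("c1", c(101, 101, 301), c(250, 250, 400), sl)
  dep <- depthFromAnchors(hits)
  v <- as.numeric(dep[["c1"]])
  expect_equal(sum(v), sum(GenomicRanges::width(hits)))
  expect_equal(unique(v[101:250]), 2)
  expect_equal(unique(v[301:400]), 1)
  expect_equal(sum(v[-c(101:250, 301:400)]), 0)
  bad <- GenomicRanges::GRanges("c1", IRanges::IRanges(990, 1100))
  expect_error(depthFromAnchors(bad, seqlengths = sl), "bounds")
})

test_that("copy-number ratios follow depth arithmetic and scale invariance", {
  sl <- c(c1 = 2000L)
  hits <- c(grFor("c1", rep(1, 60), rep(500, 60), sl),
            grFor("c1", rep(1001, 30), rep(1500, 30), sl))
  dep <- depthFromAnchors(hits)
  target <- grFor("c1", 1, 500, sl)
  control <- grFor("c1", 1001, 1500, sl)
  cn <- copyNumberRatio(dep, target, control)
  expect_equal(copyRatio(cn), 2)
  expect_equal(copyRatio(copyNumberRatio(dep, control, control)), 1)
  # doubling every depth leaves the ratio unchanged
  dep2 <- depthFromAnchors(c(hits, hits))
  expect_equal(copyRatio(copyNumberRatio(dep2, target, control)), 2)
  empty <- grFor("c1", 1600, 1900, sl)
  expect_error(copyNumberRatio(dep, target, empty), "insufficient")
})

test_that("log2 profiles are zero under equality and global scaling", {
  set.seed(30)
  base <- S4Vectors::Rle(as.integer(rpois(50000, 30)))
  test <- IRanges::RleList(c1 = base)
  ref2 <- IRanges::RleList(c1 = base * 2L)
  prof <- windowedLog2Ratio(test, test, window = 1000L)
  expect_true(all(prof@windows$log2Ratio == 0))
  profScaled <- windowedLog2Ratio(ref2, test, window = 1000L)
  expect_true(all(abs(profScaled@windows$log2Ratio) < 1e-3))
  other <- IRanges::RleList(cX = base)
  expect_error(windowedLog2Ratio(test, other), "contigs")
})

test_that("a duplicated region shows as a +1 log2 step", {
  set.seed(31)
  n <- 200000L
  ref <- as.integer(rpois(n, 30))
  test <- as.integer(rpois(n, 30))
  dup <- 100001:120000
  test[dup] <- as.integer(rpois(length(dup), 60))
  prof <- windowedLog2Ratio(IRanges::RleList(c1 = S4Vectors::Rle(test)),
                            IRanges::RleList(c1 = S4Vectors::Rle(ref)),
                            window = 1000L)
  lr <- prof@windows$log2Ratio
  inDup <- GenomicRanges::start(prof@windows) >= 100001 &
    GenomicRanges::end(prof@windows) <= 120000
  # library-size normalisation shifts the baseline by -log2(1.1); the
  # duplication contrast against that baseline is +1
  contrast <- mean(lr[inDup]) - mean(lr[!inDup])
  expect_lt(abs(contrast - 1), 0.05)
  expect_true(all(abs(lr[inDup] - mean(lr[inDup])) < 0.2))
  expect_true(all(abs(lr[!inDup] - mean(lr[!inDup])) < 0.2))
  seg <- segmentProfile(prof)
  segs <- cnvSegments(seg)
  base <- min(segs$meanLog2)
  gained <- segs[segs$meanLog2 > base + 0.5]
  expect_equal(length(gained), 1L)
  expect_lt(abs(GenomicRanges::start(gained) - 100001), 2001)
  expect_lt(abs(GenomicRanges::end(gained) - 120000), 2001)
})

test_that("constant profiles yield one segment and short profiles do not split", {
  flat <- windowedLog2Ratio(IRanges::RleList(c1 = S4Vectors::Rle(5L, 30000)),
                            IRanges::RleList(c1 = S4Vectors::Rle(5L, 30000)))
  seg <- segmentProfile(flat)
  expect_equal(length(cnvSegments(seg)), 1L)
  expect_equal(cnvSegments(seg)$meanLog2, 0)
})

test_that("binary segmentation recovers a step breakpoint within 2 windows", {
  set.seed(32)
  hits <- 0L
  for (i in 1:20) {
    x <- c(rnorm(100, 0, 0.1), rnorm(100, 1, 0.1))
    sp <- taltkit:::.bestSplit(x, 5L)
    if (abs(sp$split - 100L) <= 2L) hits <- hits + 1L
  }
  expect_equal(hits, 20L)
})

test_that("the chosen split matches an exhaustive single-breakpoint search", {
  set.seed(33)
  exhaustive <- function(x, minSeg) {
    n <- length(x)
    rss <- function(v) sum((v - mean(v))^2)
    cand <- minSeg:(n - minSeg)
    tot <- vapply(cand, function(j) rss(x[1:j]) + rss(x[(j + 1):n]), numeric(1))
    cand[which.min(tot)]
  }
  for (i in 1:50) {
    x <- rnorm(30) + rep(c(0, sample(c(0, 1, 2), 1)), times = c(12, 18))
    expect_equal(taltkit:::.bestSplit(x, 5L)$split, exhaustive(x, 5L))
  }
})

test_that("no adjacent segment pair would merge at lower penalised cost", {
  set.seed(34)
  x <- c(rnorm(60, 0, 0.2), rnorm(40, 1.2, 0.2), rnorm(50, 0.4, 0.2))
  prof <- windowedLog2Ratio(
    IRanges::RleList(c1 = S4Vectors::Rle(1L, 150000)),
    IRanges::RleList(c1 = S4Vectors::Rle(1L, 150000)))
  prof@windows$log2Ratio <- x
  pen <- 0.5
  seg <- segmentProfile(prof, minSegment = 5L, penalty = pen)
  segs <- cnvSegments(seg)
  rss <- function(v) sum((v - mean(v))^2)
  if (length(segs) > 1L) {
    bounds <- cumsum(segs$nWindows)
    starts <- c(1L, head(bounds, -1L) + 1L)
    for (i in seq_len(length(segs) - 1L)) {
      a <- x[starts[i]:bounds[i]]
      b <- x[starts[i + 1L]:bounds[i + 1L]]
      merged <- rss(c(a, b))
      expect_gt(merged + 1e-12, rss(a) + rss(b) + pen)
    }
  }
  expect_gte(length(segs), 2L)
})

test_that("pre-ALT versus pre-ALT comparisons stay flat (no-CNV null)", {
  res <- smallPreAnalysis()
  # an independent pre-ALT read set from the same lineage
  reads2 <- simulateReads(smallPre(), stream = "reads_replicate")
  allSeqs <- c(as.character(reads2@mate1), as.character(reads2@mate2))
  names(allSeqs) <- c(paste0(names(reads2@mate1), "/1"),
                      paste0(names(reads2@mate2), "/2"))
  set.seed(35)
  hits2 <- mapReads(smallIndex(), allSeqs, tieBreak = "random")
  dep2 <- depthFromAnchors(hits2)
  prof <- segmentProfile(windowedLog2Ratio(dep2, res$depth))
  expect_true(all(abs(cnvSegments(prof)$meanLog2) <= 0.3))
})
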
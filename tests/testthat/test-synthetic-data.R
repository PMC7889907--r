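test_that("configuration invariants are enforced", {
  expect_error(simConfig(templateLength = 400L, readLength = 150L),
               "templateLength")
  expect_error(simConfig(fragmentMean = 200, readLength = 150L),
               "fragmentMean")
  expect_error(simConfig(substitutionErrorRate = 1.5), "substitutionErrorRate")
  expect_error(simConfig(selectedParalog = "C"), "selectedParalog")
  expect_error(simConfig(chromLength = 20000L), "chromLength")
  expect_s4_class(smallConfig(), "SimConfig")
})

test_that("pre-ALT genome has two template copies per haploid genome", {
  sim <- smallPre()
  seg <- truthSegments(sim)
  tr <- simTruth(sim)
  perHap <- table(GenomicRanges::seqnames(seg)[grepl("^template_", seg$label)])
  # one interstitial A on chr1, one subterminal B on chr2, per haplotype
  expect_equal(sum(perHap), 4L)
  expect_equal(tr@copyNumber, 2)
  expect_setequal(unique(seg$label[grepl("^template_", seg$label)]),
                  c("template_A", "template_B"))
  # the subterminal B copy is preceded by a spacer of telomere units
  chr2 <- seg[GenomicRanges::seqnames(seg) == "chr2_h1"]
  chr2 <- chr2[order(GenomicRanges::start(chr2))]
  iB <- which(chr2$label == "template_B")
  expect_equal(chr2$label[iB - 1L], "spacer")
  expect_equal(GenomicRanges::width(chr2)[iB - 1L], 8L * 6L)
  expect_equal(chr2$label[iB + 1L], "telomere_repeat")
})

test_that("zero marker count makes the paralogs identical", {
  cfg <- smallConfig(paralogMarkerCount = 0L)
  sim <- buildPreAltGenome(cfg)
  seg <- truthSegments(sim)
  g <- genomeSequences(sim)
  tA <- seg[seg$label == "template_A" &
              GenomicRanges::seqnames(seg) == "chr1_h1"]
  tB <- seg[seg$label == "template_B" &
              GenomicRanges::seqnames(seg) == "chr2_h1"]
  sA <- as.character(Biostrings::subseq(g[["chr1_h1"]],
                                        GenomicRanges::start(tA),
                                        GenomicRanges::end(tA)))
  sB <- as.character(Biostrings::subseq(g[["chr2_h1"]],
                                        GenomicRanges::start(tB),
                                        GenomicRanges::end(tB)))
  expect_identical(sA, sB)
  expect_equal(nrow(markerSites(sim)), 0L)
})

test_that("fixed seed reproduces byte-identical FASTA output", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  p1 <- writeSimulation(buildAltGenome(smallConfig()), d1)
  p2 <- writeSimulation(buildAltGenome(smallConfig()), d2)
  expect_identical(readLines(p1["genome"]), readLines(p2["genome"]))
  expect_identical(readLines(p1["reference"]), readLines(p2["reference"]))
  r1 <- simulateReads(buildAltGenome(smallConfig()))
  f1 <- file.path(d1, "r1.fastq"); f2 <- file.path(d1, "r2.fastq")
  writeReadsFastq(r1, f1, f2)
  r2 <- simulateReads(buildAltGenome(smallConfig()))
  g1 <- file.path(d2, "r1.fastq"); g2 <- file.path(d2, "r2.fastq")
  writeReadsFastq(r2, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
  # round trip through FASTQ preserves the pairs
  back <- readPairedFastq(f1, f2)
  expect_identical(as.character(back@mate1), as.character(r1@mate1))
})

test_that("post-ALT truth is internally consistent", {
  sim <- smallPost()
  tr <- simTruth(sim)
  cfg <- sim@config
  seg <- truthSegments(sim)
  nt <- sum(grepl("^template_", seg$label))
  expect_equal(tr@copyNumber, nt / 2)
  expect_equal(tr@copyNumber, 1 + cfg@nChromosomes * cfg@altCopiesPerEnd)
  expect_identical(tr@expectedJunction, "HEAD_TO_TAIL")
  # arrays are built from the selected paralog only
  arr <- seg[grepl("^template_", seg$label) &
               GenomicRanges::start(seg) > cfg@chromLength / 2]
  expect_true(all(arr$label == paste0("template_", cfg@selectedParalog)))
  # segments tile every contig (validity already enforces; spot-check sum)
  expect_equal(sum(GenomicRanges::width(seg)),
               sum(Biostrings::width(genomeSequences(sim))))
  # per-end telomere base counts recomputed from segments match the truth
  chr1seg <- seg[GenomicRanges::seqnames(seg) == "chr1_h1"]
  chr1seg <- chr1seg[order(GenomicRanges::start(chr1seg))]
  lastSub <- max(which(chr1seg$label == "subtelomere"))
  endBases <- sum(GenomicRanges::width(chr1seg)[
    seq(lastSub + 1L, length(chr1seg))][
      chr1seg$label[seq(lastSub + 1L, length(chr1seg))] %in%
        c("telomere_repeat", "spacer")])
  expect_equal(unname(tr@telomereBasesPerEnd["chr1_h1:R"]), endBases)
})

test_that("selected paralog B stamps its marker alleles into the arrays", {
  sim <- smallPost()
  mk <- markerSites(sim)
  seg <- truthSegments(sim)
  g <- genomeSequences(sim)
  arr <- seg[seg$label == "template_B" &
               GenomicRanges::seqnames(seg) == "chr1_h1"]
  expect_gt(length(arr), 0L)
  s <- as.character(Biostrings::subseq(g[["chr1_h1"]],
                                       GenomicRanges::start(arr)[1],
                                       GenomicRanges::end(arr)[1]))
  expect_identical(vapply(mk$templatePos, function(p) substr(s, p, p),
                          character(1)),
                   mk$alleleB)
})

test_that("reversing the template orientation flips the expected call", {
  fwd <- buildAltGenome(smallConfig())
  rev <- buildAltGenome(smallConfig(templateOrientation = "reverse"))
  expect_identical(simTruth(fwd)@expectedOrientation, "FORWARD")
  expect_identical(simTruth(rev)@expectedOrientation, "REVERSE")
  seg <- truthSegments(rev)
  arr <- seg[seg$label == "template_B"]
  expect_true(all(as.character(GenomicRanges::strand(arr)) == "-"))
})

test_that("read count follows coverage arithmetic and reads are error-free substrings at rate 0", {
  cfg <- smallConfig(substitutionErrorRate = 0)
  sim <- buildPreAltGenome(cfg)
  reads <- simulateReads(sim)
  totalBases <- sum(Biostrings::width(genomeSequences(sim)))
  expect_equal(length(reads),
               round(totalBases * cfg@coverage / (2 * cfg@readLength)))
  # every read (or its reverse complement) occurs in its genome
  hay <- paste(as.character(genomeSequences(sim)), collapse = "#")
  idx <- sample.int(length(reads), 60L)
  for (s in as.character(reads@mate1[idx])) {
    expect_true(grepl(s, hay, fixed = TRUE) ||
                  grepl(rcChar(s), hay, fixed = TRUE))
  }
  for (s in as.character(reads@mate2[idx])) {
    expect_true(grepl(s, hay, fixed = TRUE) ||
                  grepl(rcChar(s), hay, fixed = TRUE))
  }
})

test_that("realised depth over an interstitial window is close to the configured coverage", {
  sim <- smallPre()
  reads <- smallPreReads()
  cfg <- sim@config
  # count read bases landing in a 10 kb window of the chr1 body, by direct
  # coordinate bookkeeping on error-free placement via mapping
  hits <- mapReads(smallIndex(), reads@mate1, tieBreak = "unique")
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 20000))
  dep <- depthFromAnchors(hits)
  v <- as.numeric(dep[["chr1"]][10001:20000])
  # mate1 alone carries half the pairs' bases; two haplotypes map together:
  # expected depth = coverage (per haplotype base) * 2 haplotypes / 2 mates
  expect_lt(abs(mean(v) - cfg@coverage) / cfg@coverage, 0.1)
})
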
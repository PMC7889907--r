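mkSites <- function(pos, ref, alt, sl, paralog = NULL) {
  gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(pos, pos),
                               refAllele = ref, altAllele = alt,
                               seqlengths = sl)
  if (!is.null(paralog)) gr$paralog <- paralog
  gr
}

test_that("pileups count strand-corrected allele observations", {
  sl <- c(c1 = 1000L)
  # a 20-base reference word placed at 101..120; position 111 reads "G"
  refWord <- "ACGTACGTACGTACGTACGT"
  mutated <- refWord
  substr(mutated, 11, 11) <- "T"
  reads <- c(r1 = refWord, r2 = refWord, r3 = mutated, r4 = rcChar(refWord))
  hits <- GenomicRanges::GRanges(
    "c1", IRanges::IRanges(rep(101, 4), rep(120, 4)),
    strand = c("+", "+", "+", "-"),
    readId = names(reads), seqlengths = sl)
  sites <- mkSites(111L, "G", "T", sl)
  pile <- pileupAlleles(hits, reads, sites)
  # r1, r2 forward ref; r3 forward alt; r4 minus-strand read contributing the
  # complement of its stored base -> ref
  expect_equal(pile$refDepth, 3L)
  expect_equal(pile$altDepth, 1L)
  expect_equal(pile$otherDepth, 0L)
  # a site covered by no read
  empty <- pileupAlleles(hits, reads, mkSites(500L, "A", "C", sl))
  expect_equal(empty$refDepth + empty$altDepth + empty$otherDepth, 0L)
  oob <- mkSites(5000L, "A", "C", NULL)
  expect_error(pileupAlleles(hits, reads, oob), "bounds")
})

test_that("zygosity calls respect depth and homozygosity thresholds", {
  d <- S4Vectors::DataFrame(refDepth = c(10L, 0L, 2L, 20L, 1L),
                            altDepth = c(10L, 20L, 1L, 1L, 0L))
  z <- callZygosity(d)
  expect_equal(z$call, c("HET", "HOM_ALT", "NOCALL", "HOM_REF", "NOCALL"))
  expect_equal(z$altFrequency[1], 0.5)
})

test_that("loh gradients bin homozygous fractions from the chromosome end", {
  allHom <- S4Vectors::DataFrame(contig = "c1", pos = c(10L, 150L, 900L),
                                 call = c("HOM_ALT", "HOM_REF", "HOM_ALT"))
  g <- lohGradient(allHom, chromLength = 1000L, bin = 100L)
  expect_true(all(g$homFraction[g$n > 0] == 1))
  expect_true(all(is.na(g$homFraction[g$n == 0])))
  allHet <- S4Vectors::DataFrame(contig = "c1", pos = c(10L, 900L),
                                 call = c("HET", "HET"))
  g2 <- lohGradient(allHet, chromLength = 1000L, bin = 100L)
  expect_true(all(g2$homFraction[g2$n > 0] == 0))
  # distance is measured from the distal (right) end by default
  one <- lohGradient(S4Vectors::DataFrame(contig = "c1", pos = 995L,
                                          call = "HET"),
                     chromLength = 1000L, bin = 100L)
  expect_equal(one$n[1], 1L)
})

test_that("a simulated subtelomeric gradient is recovered monotonically", {
  set.seed(40)
  rhos <- vapply(1:10, function(i) {
    pos <- sort(sample.int(1000000L, 400L))
    pHom <- 1 - (1000000 - pos) / 1000000   # rises towards the end
    call <- ifelse(runif(400) < pHom, "HOM_ALT", "HET")
    g <- lohGradient(S4Vectors::DataFrame(contig = "c1", pos = pos,
                                          call = call),
                     chromLength = 1000000L, bin = 100000L)
    ok <- !is.na(g$homFraction)
    cor(g$distanceStart[ok], g$homFraction[ok], method = "spearman")
  }, numeric(1))
  expect_true(all(rhos < -0.8))
})

test_that("longitudinal selection follows AF-shift and copy-number rules", {
  mkCalls <- function(af, label = "B") {
    S4Vectors::DataFrame(paralog = rep(label, 5),
                         altFrequency = rep(af, 5),
                         call = rep("HET", 5))
  }
  # rising B-private allele with amplification: select B
  res <- selectAmplifiedParalog(list(mkCalls(0.5), mkCalls(0.95)), c(2, 8))
  expect_equal(selectedParalog(res), "B")
  expect_equal(res@scoreB, 0.45)
  # flat frequencies, flat copy number: nothing selected
  flat <- selectAmplifiedParalog(list(mkCalls(0.5), mkCalls(0.5)), c(2, 2))
  expect_equal(selectedParalog(flat), "none")
  # falling alt frequency at B-labelled sites means paralog A took over
  resA <- selectAmplifiedParalog(list(mkCalls(0.5), mkCalls(0.05)), c(2, 8))
  expect_equal(selectedParalog(resA), "A")
  # a copy-number decrease vetoes the call
  veto <- selectAmplifiedParalog(list(mkCalls(0.5), mkCalls(0.95)), c(8, 2))
  expect_equal(selectedParalog(veto), "none")
  expect_error(selectAmplifiedParalog(list(mkCalls(0.5)), 2), "timepoints")
  noLab <- S4Vectors::DataFrame(paralog = NA_character_, altFrequency = 0.5,
                                call = "HET")
  expect_error(selectAmplifiedParalog(list(noLab, noLab), c(2, 2)),
               "labelled")
})

test_that("selection is symmetric under label swap", {
  callsT1 <- S4Vectors::DataFrame(paralog = c("A", "B", "B"),
                                  altFrequency = c(0.5, 0.5, 0.5),
                                  call = rep("HET", 3))
  callsT2 <- S4Vectors::DataFrame(paralog = c("A", "B", "B"),
                                  altFrequency = c(0.05, 0.95, 0.92),
                                  call = rep("HOM_ALT", 3))
  res <- selectAmplifiedParalog(list(callsT1, callsT2), c(2, 8))
  swap <- function(x) {
    x$paralog <- ifelse(x$paralog == "A", "B", "A")
    x
  }
  resSwapped <- selectAmplifiedParalog(list(swap(callsT1), swap(callsT2)),
                                       c(2, 8))
  expect_equal(selectedParalog(res), "B")
  expect_equal(selectedParalog(resSwapped), "A")
})

test_that("paralog allele frequencies are conserved in the simulated pileup", {
  post <- smallPostAnalysis()
  pre <- smallPreAnalysis()
  zygPre <- pre$zygosity
  zygPost <- post$zygosity
  # pre-ALT: one copy of each paralog -> B-private alleles near 0.5
  expect_true(all(abs(zygPre$altFrequency - 0.5) < 0.15))
  # post-ALT: B amplified -> near fixation of the B allele
  expect_true(all(zygPost$altFrequency > 0.8))
  # AF_A + AF_B is 1 by construction where only the two alleles are seen
  afSum <- zygPost$altFrequency + (1 - zygPost$altFrequency)
  expect_true(all(abs(afSum - 1) < 1e-12))
  sel <- selectAmplifiedParalog(list(zygPre, zygPost),
                                c(copyRatio(pre$copyNumber),
                                  copyRatio(post$copyNumber)))
  expect_equal(selectedParalog(sel), selectedParalog(simTruth(smallPost())))
})
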
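# Shared fixtures, computed once per test run and cached.
# Small-scale study conditions used by most unit tests: the architecture of
# the default configuration scaled down (2 kb template, 4 copies per end,
# 120 bp reads so junction reads can span probe + 8-unit spacer + probe).
.fixtureEnv <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtureEnv)) {
    assign(name, build(), envir = .fixtureEnv)
  }
  get(name, envir = .fixtureEnv)
}

smallConfig <- function(seed = 42L, ...) {
  args <- list(seed = seed, chromLength = 60000L, templateLength = 2000L,
               paralogMarkerCount = 6L, preAltTelomereLength = 1500L,
               altCopiesPerEnd = 4L, readLength = 120L, fragmentMean = 320,
               fragmentSd = 30, coverage = 30)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(simConfig, args)
}

smallPre <- function() fixture("smallPre", function() {
  buildPreAltGenome(smallConfig())
})

smallPost <- function() fixture("smallPost", function() {
  buildAltGenome(smallConfig())
})

smallPreReads <- function() fixture("smallPreReads", function() {
  simulateReads(smallPre())
})

smallPostReads <- function() fixture("smallPostReads", function() {
  simulateReads(smallPost())
})

smallIndex <- function() fixture("smallIndex", function() {
  buildSeedIndex(referenceSequences(smallPre()))
})

smallPostAnalysis <- function() fixture("smallPostAnalysis", function() {
  analyzeSample(smallPost(), reads = smallPostReads(), index = smallIndex())
})

smallPreAnalysis <- function() fixture("smallPreAnalysis", function() {
  analyzeSample(smallPre(), reads = smallPreReads(), index = smallIndex())
})

# Random DNA string helper for property tests.
randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

rcChar <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
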
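# Shared helpers (internal).

# Uniform random DNA of length n, drawn from the current RNG stream.
.randomDNA <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Reverse complement for plain character vectors.
.rc <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# A telomere-repeat tract of exactly `bases` bases built from `unit`,
# truncated mid-unit if bases is not a multiple of the unit length.
.repeatTract <- function(unit, bases) {
  if (bases <= 0L) return("")
  substr(strrep(unit, ceiling(bases / nchar(unit))), 1L, bases)
}

# Derive a per-stage seed from the global seed and a stage name, so stages
# can be rerun in isolation with identical behaviour.  Kept below 2^31.
.derivedSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

.stopConfig <- function(...) {
  stop("configuration error: ", ..., call. = FALSE)
}

.stopData <- function(...) {
  stop("data error: ", ..., call. = FALSE)
}

# Complement of single-character bases (vectorised).
.compBase <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

# md5 of a serialised R object; used for report provenance.
.objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}
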
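---
title: "Discovering non-telomeric ALT template elements from paired-end WGS"
author: "taltkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering non-telomeric ALT template elements from paired-end WGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Telomeres are normally arrays of the canonical vertebrate repeat TTAGGG,
maintained by telomerase.  When telomerase is absent, some cell lineages
survive telomere crisis by alternative lengthening of telomeres (ALT).  In
the mouse embryonic stem cell system this package models, ALT does not merely
amplify telomere repeats: a specific ~7.4 kb subtelomeric element -- a
template for ALT (mTALT) -- is copied into chromosome ends as tandem
head-to-tail arrays interleaved with short telomere-repeat spacers.  The
element exists as two near-identical paralogs, one interstitial (the copy
present in the reference assembly, on chr13 in the mouse) and one subterminal
(behind a short telomere tract, on chr11), distinguishable only by a handful
of private SNP alleles; exactly one of them -- the subterminal copy -- is
amplified.

Everything about that architecture is visible in ordinary paired-end WGS, if
you know where to look:

* **Telomere content.**  Reads made of TTAGGG/CCCTAA repeats measure total
  telomeric sequence; normalised by depth of coverage they give a telomere
  length per chromosome end.
* **Single telomeric pairs.**  A pair with exactly one telomeric mate has its
  other mate anchored in whatever sequence borders a telomere.  After ALT
  activation those anchors pile up on the template locus.
* **Strand-typed anchors.**  Telomere repeats read TTAGGG on the forward
  strand everywhere in a uniformly oriented array, so whether the telomeric
  mate of a Single pair is G-rich or C-rich as sequenced tells you on which
  side of the anchored mate the telomere lies -- and hence the orientation of
  the template in the array.
* **Junction reads.**  Single reads spanning a copy boundary contain the
  template's tail, a countable number of telomere units, then its head --
  the in-silico analogue of a directional junction PCR.
* **Depth ratios.**  The template's copy number is the mean depth over the
  locus divided by the mean depth over an equal-length single-copy control
  interval on the same chromosome.
* **Pooled pileup allele frequencies.**  The two paralogs cross-map onto the
  single reference locus, so the pileup there pools them; the frequency of a
  paralog-private allele tracks that paralog's share of template dosage, and
  its trajectory over population doublings identifies the amplified copy.

taltkit implements each of these measurements as an independently testable
stage, plus a simulator that generates pre-ALT and post-ALT genomes with
machine-readable ground truth, so the whole pipeline can be validated by
parameter recovery.

## The simulator and what it does (and does not) emulate

`buildPreAltGenome()` and `buildAltGenome()` construct a small diploid genome
(default 2 chromosomes x 500 kb, two identical haplotypes each -- the
subterminal template locus is homozygous in the modelled line).  Pre-ALT
chromosome ends carry 5,000 bp of telomere repeats; paralog A sits
interstitially on chromosome 1 and paralog B subterminally on chromosome 2,
joined to the subtelomere by eight telomere units -- the junction structure
reported for the subterminal locus.  Post-ALT, every q-arm end is rebuilt as
eight tandem copies of the selected paralog (default B), each preceded by an
eight-unit telomere spacer and capped by a short terminal tract (10 units; a
value the underlying biology does not pin down, configurable).  The spacer
length between tandem copies is likewise not observable by junction PCR, so
the default mirrors the one junction whose spacer is known (eight units) and
is exposed as configuration rather than asserted.

The mapping reference returned with each simulation deliberately contains a
*single* template copy (paralog A's interstitial locus), exactly as a
standard reference assembly would: the subterminal paralog is a
strain-specific structural variant.  This is what makes the pooled-pileup
logic work, and it avoids unique-best mapping ties between near-identical
paralogs that would otherwise discard all template anchors.

`simulateReads()` draws `round(totalBases * coverage / (2 * readLength))`
fragments with uniform starts and Normal(450, 50) lengths, reports mate 2 as
the reverse complement of the fragment end, randomises which physical mate is
labelled 1, applies independent per-base substitutions (default 0.002), and
assigns a constant Q30 quality -- the classification stages are
quality-agnostic, so a realistic quality model would add nothing the tests
could detect.  One seed in the configuration drives every draw through
derived per-stage streams, so outputs are reproducible bit for bit.

Deliberately not emulated: indels and structural sequencing errors (the
aligner is ungapped; reads carrying indels would simply be lost), GC bias,
optical duplicates, quality decay along reads, and haplotype heterozygosity
outside the template markers.  Passing recovery tests therefore show the
pipeline's logic is correct under clean substitution-only noise; they do not
certify performance on real libraries with indel errors or biased coverage.

## Stage models and tunable parameters

**Motif classification** (`classifyPairs()`).  A mate is telomeric when
TTAGGG or its complement CCCTAA occurs at least `threshold = 3` times
(non-overlapping, exact, case-insensitive); both motifs at threshold makes it
AMBIGUOUS -- counted as telomeric for content, excluded from strand-typed
orientation evidence.  Variant repeats (TCAGGG, TGAGGG) are out of scope.
Reads are scanned as written; reverse-complement scanning is redundant
because both strand motifs are counted.

**Telomere content** (`estimateTelomereContent()`).  `L = B_tel / (d * E)`
with `d = B_total / G`: telomeric bases, normalised by mean depth, split
across `E` chromosome ends.  A full mate length is credited for every
telomeric mate, so boundary mates overcount slightly; chromosome ends are
undersampled within one fragment length for the opposite reason.  Recovery
on simulated pre-ALT libraries is within a few percent.

**Anchor mapping** (`buildSeedIndex()`, `mapReads()`).  A canonical k-mer
index (`k = 15`) over both strands; k-mers occurring more than `maxOcc = 64`
times (telomere repeats and other high-copy sequence) are not used as seeds
-- reads from such sequence are inherently ambiguous and would fall to the
tie rule anyway.  Each read is seeded with its non-overlapping k-mers plus
the terminal k-mer, so any read with at most `floor(0.05 * length)`
substitutions retains a clean seed.  Candidates are scored by full-length
ungapped comparison (score = matches − mismatches).  For anchor *evidence*
the best placement must be unique -- ambiguity discards the read, which keeps
paralog cross-talk out of the evidence.  For *depth* (`tieBreak = "random"`)
ties are resolved uniformly at random from a seeded stream, mirroring
standard multi-mapper handling: evidence purity versus unbiased coverage.

**Region calling** (`collectCandidateRegions()`).  Windows (1 kb) are tested
against a Poisson null with mean `N * w / L_mappable`, Bonferroni-corrected
across windows at `alpha = 0.01`.  Telomere-adjacent evidence flanks *both*
ends of a template element, so significant windows within `maxGap = 10 kb`
(the scale of one element) merge into a single candidate region; with strict
adjacency the two flanks of a locus would surface as separate 1 kb fragments.

**Orientation** (`callOrientation()`).  Within `endMargin = 1 kb` of a
region's 5'/3' boundaries, count anchors by the strand type of their
telomeric partner.  Because telomere repeats read TTAGGG on the forward
strand, a telomeric mate upstream of its anchored partner is G-typed;
a forward-inserted template therefore shows G-partners at its 5' end and
C-partners at its 3' end.  FORWARD requires both proportions to reach
`tau = 0.9`; fewer than `minInformative = 20` informative anchors is NOCALL;
anything else INCONSISTENT.  The FORWARD/REVERSE labels are a convention --
nothing in the underlying figures fixes a sign -- so the convention is
defined by this rule and validated against simulator truth.

**Junctions** (`scanJunctionReads()`).  HEAD/TAIL are the first/last
`probeLen = 30` bases of the template; matching is exact, like PCR primers:
at an 0.002 substitution rate most junction reads still match and
specificity, not sensitivity, is the point.  A junction read needs
`2 * probeLen + 6 * spacerUnits` bases, so at the default eight-unit spacer
reads must be at least 108 bp.  Spacer units are counted exactly; the
histogram is simulator-validated only, since the underlying PCR cannot bound
spacer length.

**Copy number** (`copyNumberRatio()`).  Depth ratio of the template locus
against an equal-length single-copy interval on the same chromosome (recorded
in simulator truth; in the mouse data the analogous control is an interval
~10 Mb proximal on chr13).  Against a single-copy-per-haploid control the
ratio reads as copies per haploid genome: a two-locus homozygous template
reads ~2 pre-ALT and `1 + nChromosomes * altCopiesPerEnd` (17 at defaults)
post-ALT.  The raw ratio is reported without subtracting pre-existing
copies.  Reads straddling array-copy boundaries fail the mismatch cap and
are lost, depressing the measured ratio by roughly `readLength /
templateLength` per copy (~2% at defaults).

**CNV** (`windowedLog2Ratio()`, `segmentProfile()`).  Library-size-normalised
per-window log2 ratios with a 0.5 pseudocount, segmented by recursive binary
segmentation: each split maximises the between-segment residual-sum-of-squares
reduction and is accepted only when that reduction exceeds a BIC-style
penalty `2 * var * log(n)` (noise variance estimated robustly from successive
window differences, `(mad(diff(x)) / sqrt(2))^2`).  The RSS-reduction
statistic -- rather than a pooled-variance t -- makes the chosen split
identical to an exhaustive single-breakpoint RSS search, which is how it is
oracle-tested.  This is deliberately not circular binary segmentation;
at these problem sizes a step detector with a merge-cost guarantee is
sufficient, and the penalty is mildly permissive (near-zero-noise profiles
can split a flat region; segment means are unaffected).  `minSegment = 5`
windows prevents singleton segments; profiles shorter than `minSegment`
return one segment.

**Zygosity and selection** (`callZygosity()`, `selectAmplifiedParalog()`).
Calls need `minDepth = 5` informative bases; allele frequency above
`homCut = 0.9` is HOM_ALT, below `1 - homCut` HOM_REF, otherwise HET.  These
thresholds are this package's own; the original analysis used a full
genotyper with hard filters, which is not reproduced.  Paralog p's private
allele frequency `AF_p` is averaged over labelled marker sites (at a site
labelled with the other paralog, `1 - AF` is used); the selection rule is
`S_p = AF_p(last) - AF_p(first) >= 0.25`, `AF_p(last) >= 0.75`, and a
non-decreasing copy-number ratio (5% relative slack absorbs depth noise,
which would otherwise veto legitimate calls on exact monotonicity).
Timepoints are user-ordered by population doubling; no dating model.
`lohGradient()` bins homozygous fractions by distance from the distal
chromosome end to expose subtelomeric loss-of-heterozygosity.

**Digestion** (`digestSequence()`).  AluI (AG^CT), MboI (^GATC) and HinfI
(G^ANTC) -- the terminal-restriction-fragment enzymes, none of which cuts
TTAGGG -- with N matching any base.  A single-strand scan suffices because
all built-ins are palindromic; non-palindromic user enzymes trigger an
automatic both-strand scan with the mirrored offset.  Cut positions model the
top-strand cut, so staggered cutters mirror under reverse complement with a
`patternLength - 2 * cutOffset` shift (exact for blunt AluI).  Sequences are
linear; telomeric arrays are not circular.  On a post-ALT chromosome end the
cut set recurs with the array period (template plus spacer), the discrete-band
logic of a TRF blot.

## An end-to-end run

```{r pipeline}
library(taltkit)
report <- runPipeline(list(seed = 1))
report$postALT$copyNumberRatio   # ~17 at defaults
report$postALT$topRegion         # the template locus, FORWARD
report$selection$selected        # "B"
```

`runPipeline()` builds both phases of one simulated lineage, analyses each
(classification, content, anchoring, regions and orientation, junctions,
depth and copy number, marker pileup), then compares the two depth tracks as
a CNV profile and applies the longitudinal selection rule.  One global seed
feeds derived per-stage seeds (stage names hashed into the stream), so any
stage can be rerun in isolation with identical behaviour, and a rerun with
the same configuration reproduces the report exactly.

## Validation strategy and problem sizes

The test suite validates each primitive against an independent oracle
(motif counting against a sliding-window scan on 1,000 random strings; read
placement against an exhaustive full-scan best alignment of 200 mutated reads
on 2 kb references; segmentation splits against exhaustive single-breakpoint
search on 30-window profiles), property-style invariants (reverse-complement
symmetries, partition completeness, fragment-length conservation, refinement
monotonicity, depth-scaling invariance, the Bonferroni false-region rate
under 100 null simulations), and whole-pipeline parameter recovery.  Unit
tests run on a scaled-down architecture (60 kb chromosomes, 2 kb template,
4 copies per end, 120 bp reads -- long enough to span a junction);
recovery checks run at the reference conditions of 2 x 500 kb chromosomes at
30x with the 7,370 bp template, across multiple seeds, and the paralog
selection rule is exercised over an amplification grid (2, 4 and 8 copies per
end, i.e. dosage ratios of 5, 9 and 17 against the 2-copy baseline) on
120 kb chromosomes.

## Known limitations

* Ungapped alignment: indel-bearing reads are lost rather than placed.
* Exact junction probes trade sensitivity for specificity; heavily mutated
  junctions go uncounted.
* The Poisson region model assumes uniform mappability outside N-runs.
* Binary segmentation is not circular binary segmentation; on long flat
  profiles with near-zero noise it can oversegment (means are unaffected).
* The simulator's homozygous-architecture assumption means zygosity recovery
  is only exercised at template marker sites, not genome-wide.
* SAM/BAM import is an extension point: anchors are produced and consumed as
  GRanges/TSV.
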
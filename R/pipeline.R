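#' @include AllClasses.R simulate.R telreads.R anchors.R junctions.R quant.R
#' @include zygosity.R digest.R io.R
NULL

.defaultStageParams <- function() {
  list(
    classify = list(threshold = 3L, unit = "TTAGGG"),
    anchors = list(k = 15L, maxOcc = 64L, maxMismatchFrac = 0.05),
    regions = list(window = 1000L, alpha = 0.01, maxGap = 10000L),
    orientation = list(endMargin = 1000L, tau = 0.9, minInformative = 20L),
    junctions = list(probeLen = 30L, maxSpacerUnits = 30L, dominance = 0.8),
    quant = list(window = 1000L, pseudocount = 0.5, minSegment = 5L),
    zygosity = list(minDepth = 5L, homCut = 0.9),
    selection = list(minShift = 0.25, minFinalAf = 0.75, cnTolerance = 0.05)
  )
}

# Per-parameter sanity checks used by validatePipelineConfig; each returns a
# character error message or NULL.
.paramChecks <- list(
  "classify.threshold" = function(v) if (v < 1) "must be >= 1",
  "anchors.k" = function(v) if (v < 8) "must be >= 8",
  "anchors.maxOcc" = function(v) if (v < 1) "must be >= 1",
  "anchors.maxMismatchFrac" = function(v) if (v < 0 || v > 1) "must lie in [0, 1]",
  "regions.window" = function(v) if (v <= 0) "must be positive",
  "regions.alpha" = function(v) if (v <= 0 || v > 1) "must lie in (0, 1]",
  "regions.maxGap" = function(v) if (v < 0) "must be >= 0",
  "orientation.endMargin" = function(v) if (v <= 0) "must be positive",
  "orientation.tau" = function(v) if (v <= 0.5 || v > 1) "must lie in (0.5, 1]",
  "orientation.minInformative" = function(v) if (v < 1) "must be >= 1",
  "junctions.probeLen" = function(v) if (v < 10) "must be >= 10",
  "junctions.maxSpacerUnits" = function(v) if (v < 0) "must be >= 0",
  "junctions.dominance" = function(v) if (v <= 0.5 || v > 1) "must lie in (0.5, 1]",
  "quant.window" = function(v) if (v <= 0) "must be positive",
  "quant.pseudocount" = function(v) if (v < 0) "must be >= 0",
  "quant.minSegment" = function(v) if (v < 2) "must be >= 2",
  "zygosity.minDepth" = function(v) if (v < 1) "must be >= 1",
  "zygosity.homCut" = function(v) if (v <= 0.5 || v >= 1) "must lie in (0.5, 1)",
  "selection.minShift" = function(v) if (v < 0 || v > 1) "must lie in [0, 1]",
  "selection.minFinalAf" = function(v) if (v < 0 || v > 1) "must lie in [0, 1]",
  "selection.cnTolerance" = function(v) if (v < 0) "must be >= 0"
)

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or NULL (all defaults).  Every
#' parameter has a default, so an empty configuration is valid.  All
#' validation errors are collected and reported together; unknown keys
#' produce a warning and are ignored (forward compatibility).
#'
#' @param config YAML path, list, or NULL.
#' @return A [PipelineConfig-class]; on invalid input an error listing every
#'   problem at once.
#' @export
validatePipelineConfig <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("cannot read configuration file: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) .stopConfig("configuration must be a mapping")
  errors <- character(0)
  defaults <- .defaultStageParams()
  known <- c("seed", "outdir", "simulation", names(defaults))
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    warning("ignoring unknown configuration key(s): ",
            paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    errors <- c(errors, "seed: must be a single integer")
  simArgs <- config$simulation %||% list()
  simDefaults <- formals(simConfig)
  unknownSim <- setdiff(names(simArgs), names(simDefaults))
  if (length(unknownSim)) {
    warning("ignoring unknown simulation key(s): ",
            paste(unknownSim, collapse = ", "))
    simArgs <- simArgs[setdiff(names(simArgs), unknownSim)]
  }
  simArgs$seed <- simArgs$seed %||% seed
  sim <- tryCatch(do.call(simConfig, simArgs),
                  error = function(e) {
                    errors <<- c(errors, paste0("simulation: ", conditionMessage(e)))
                    NULL
                  })
  params <- defaults
  for (stage in names(defaults)) {
    user <- config[[stage]] %||% list()
    unknownP <- setdiff(names(user), names(defaults[[stage]]))
    if (length(unknownP))
      warning("ignoring unknown ", stage, " key(s): ",
              paste(unknownP, collapse = ", "))
    for (key in intersect(names(user), names(defaults[[stage]]))) {
      v <- user[[key]]
      full <- paste0(stage, ".", key)
      if (!is.numeric(v) && !is.character(v)) {
        errors <- c(errors, paste0(full, ": invalid value"))
        next
      }
      chk <- .paramChecks[[full]]
      msg <- if (!is.null(chk) && is.numeric(v)) chk(v) else NULL
      if (!is.null(msg)) errors <- c(errors, paste0(full, ": ", msg))
      else params[[stage]][[key]] <- v
    }
  }
  if (length(errors))
    .stopConfig("invalid configuration:\n  - ",
                paste(errors, collapse = "\n  - "))
  new("PipelineConfig",
      seed = as.integer(seed),
      outdir = as.character(config$outdir %||% NA_character_),
      simulation = sim,
      params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Analyse one (simulated) sample end to end
#'
#' Runs classification, telomere content estimation, single-pair anchor
#' mapping, candidate region calling with orientation, junction typing,
#' depth-based copy number and marker-site zygosity for one timepoint of a
#' simulation.  This is the per-sample half of [runPipeline()]; for real
#' data the individual stage functions are the interface.
#'
#' @param sim an [AltSimulation-class].
#' @param reads optional [PairedReads-class]; simulated from `sim` when NULL.
#' @param index optional prebuilt [SeedIndex-class] over `sim@reference`.
#' @param params stage parameter list as in [PipelineConfig-class]; missing
#'   entries take defaults.
#' @return A list with elements `classification`, `categoryCounts`,
#'   `content`, `anchorHits`, `regions`, `topRegion`, `junctionCalls`,
#'   `junctionSummary`, `depth`, `copyNumber`, `zygosity`, `index`.
#' @export
analyzeSample <- function(sim, reads = NULL, index = NULL, params = list()) {
  stopifnot(is(sim, "AltSimulation"))
  p <- utils::modifyList(.defaultStageParams(), params)
  truth <- sim@truth
  if (is.null(reads))
    reads <- .stage("simulate", simulateReads(sim))
  cls <- .stage("classify",
                classifyPairs(reads, p$classify$threshold, p$classify$unit))
  content <- .stage("content",
                    estimateTelomereContent(cls, truth@genomeSize, truth@nEnds))
  if (is.null(index))
    index <- .stage("index",
                    buildSeedIndex(sim@reference, p$anchors$k, p$anchors$maxOcc))
  # anchor evidence: the non-telomeric mate of every SINGLE pair
  single <- which(cls$category == "SINGLE")
  m1 <- cls$anchorableMate[single] == 1L
  anchorSeqs <- c(as.character(reads@mate1[single[m1]]),
                  as.character(reads@mate2[single[!m1]]))
  names(anchorSeqs) <- c(cls$id[single[m1]], cls$id[single[!m1]])
  partner <- c(cls$partnerType[single[m1]], cls$partnerType[single[!m1]])
  hits <- .stage("anchor", {
    h <- mapReads(index, anchorSeqs, p$anchors$maxMismatchFrac, "unique")
    h$partnerType <- partner[match(h$readId, names(anchorSeqs))]
    h
  })
  regions <- .stage("regions",
                    collectCandidateRegions(hits, index, p$regions$window,
                                            p$regions$alpha, p$regions$maxGap))
  if (length(regions) > 0L) {
    ori <- .stage("orient",
                  callOrientation(regions, hits, p$orientation$endMargin,
                                  p$orientation$tau,
                                  p$orientation$minInformative))
    mcols(regions) <- cbind(mcols(regions), ori)
  }
  topRegion <- if (length(regions)) regions[1] else NULL
  templateSeq <- as.character(subseq(
    sim@reference[[as.character(seqnames(truth@templateRegion))]],
    start(truth@templateRegion), end(truth@templateRegion)))
  allSeqs <- c(as.character(reads@mate1), as.character(reads@mate2))
  names(allSeqs) <- c(paste0(names(reads@mate1), "/1"),
                      paste0(names(reads@mate2), "/2"))
  jcalls <- .stage("junctions",
                   scanJunctionReads(allSeqs, templateSeq,
                                     p$junctions$probeLen, p$classify$unit,
                                     p$junctions$maxSpacerUnits))
  jsummary <- summarizeJunctions(jcalls, p$junctions$dominance)
  # unbiased depth: all reads, ambiguity resolved at random (derived seed)
  set.seed(.derivedSeed(sim@config@seed, paste0("depth_", sim@phase)))
  depthHits <- .stage("depth-map",
                      mapReads(index, allSeqs, p$anchors$maxMismatchFrac,
                               "random"))
  depth <- .stage("depth", depthFromAnchors(depthHits))
  cn <- .stage("copynum",
               copyNumberRatio(depth, truth@templateRegion, truth@controlRegion))
  mk <- truth@markers
  zyg <- NULL
  if (nrow(mk) > 0L) {
    sites <- GRanges(mk$refContig, IRanges(mk$refPos, mk$refPos),
                     refAllele = mk$alleleA, altAllele = mk$alleleB,
                     paralog = "B",
                     seqlengths = index@seqlengths)
    pile <- .stage("zygosity", pileupAlleles(depthHits, allSeqs, sites))
    zyg <- callZygosity(pile, p$zygosity$minDepth, p$zygosity$homCut)
  }
  list(phase = sim@phase, classification = cls,
       categoryCounts = pairCategoryCounts(cls), content = content,
       anchorHits = hits, regions = regions, topRegion = topRegion,
       junctionCalls = jcalls[jcalls$junctionClass != "UNCLASSIFIED", ],
       junctionSummary = jsummary, depth = depth, copyNumber = cn,
       zygosity = zyg, index = index)
}

.regionToList <- function(r) {
  if (is.null(r) || length(r) == 0L) return(NULL)
  out <- list(contig = as.character(seqnames(r)), start = start(r),
              end = end(r), anchorCount = r$anchorCount)
  if (!is.null(r$orientation)) out$orientation <- r$orientation
  out
}

#' Run the full discovery pipeline on a simulated ALT time course
#'
#' Builds the pre-ALT and post-ALT genomes of one simulated lineage, analyses
#' each timepoint with [analyzeSample()], compares the two depth tracks as a
#' windowed log2-ratio CNV profile with segmentation, and applies the
#' longitudinal paralog-selection rule.  All stage outputs are returned in a
#' machine-readable report; when `outdir` is set, report and per-stage tables
#' are also written to disk.
#'
#' @param config a [PipelineConfig-class], a YAML path, a list, or NULL (all
#'   defaults); see [validatePipelineConfig()].
#' @param outdir optional output directory (overrides the config).
#' @param force overwrite an existing non-empty output directory.
#' @return The report: a nested list with elements `preALT`, `postALT`
#'   (per-sample results), `cnv`, `selection`, `truth` and `provenance`, plus
#'   a `samples` element holding the full per-sample objects.
#' @export
runPipeline <- function(config = NULL, outdir = NULL, force = FALSE) {
  if (!is(config, "PipelineConfig")) config <- validatePipelineConfig(config)
  if (!is.null(outdir)) config@outdir <- outdir
  outdir <- if (is.na(config@outdir)) NULL else config@outdir
  if (!is.null(outdir) && dir.exists(outdir) &&
      length(list.files(outdir)) > 0L && !force)
    .stopConfig("output directory exists and is not empty (use force = TRUE)")
  p <- config@params
  simPre <- .stage("simulate", buildPreAltGenome(config@simulation))
  simPost <- .stage("simulate", buildAltGenome(config@simulation))
  index <- .stage("index", buildSeedIndex(simPre@reference, p$anchors$k,
                                          p$anchors$maxOcc))
  pre <- analyzeSample(simPre, index = index, params = p)
  post <- analyzeSample(simPost, index = index, params = p)
  cnv <- .stage("cnv", segmentProfile(
    windowedLog2Ratio(post$depth, pre$depth, p$quant$window,
                      p$quant$pseudocount),
    p$quant$minSegment))
  selection <- if (!is.null(pre$zygosity)) {
    .stage("select-paralog", selectAmplifiedParalog(
      list(pre$zygosity, post$zygosity),
      c(copyRatio(pre$copyNumber), copyRatio(post$copyNumber)),
      p$selection$minShift, p$selection$minFinalAf, p$selection$cnTolerance))
  } else NULL
  sampleReport <- function(s) {
    list(categoryCounts = as.list(s$categoryCounts),
         telomereContent = list(
           telomericBases = s$content@telomericBases,
           meanDepth = s$content@meanDepth,
           lengthPerEnd = s$content@lengthPerEnd),
         nRegions = length(s$regions),
         topRegion = .regionToList(s$topRegion),
         junctions = list(counts = as.list(s$junctionSummary$counts),
                          dominantClass = s$junctionSummary$dominantClass,
                          modalSpacer = s$junctionSummary$modalSpacer),
         copyNumberRatio = copyRatio(s$copyNumber),
         zygosityCalls = if (is.null(s$zygosity)) NULL else
           as.list(table(s$zygosity$call)))
  }
  segDf <- if (!is.null(cnvSegments(cnv))) {
    s <- cnvSegments(cnv)
    data.frame(contig = as.character(seqnames(s)), start = start(s),
               end = end(s), meanLog2 = s$meanLog2, nWindows = s$nWindows)
  } else NULL
  report <- list(
    preALT = sampleReport(pre),
    postALT = sampleReport(post),
    cnv = list(window = cnv@window, segments = segDf),
    selection = if (is.null(selection)) NULL else list(
      selected = selection@selected, scoreA = selection@scoreA,
      scoreB = selection@scoreB, trajectory = selection@trajectory),
    truth = list(
      preCopyNumber = simPre@truth@copyNumber,
      postCopyNumber = simPost@truth@copyNumber,
      selectedParalog = simPost@truth@selectedParalog,
      expectedJunction = simPost@truth@expectedJunction,
      expectedOrientation = simPost@truth@expectedOrientation),
    provenance = list(
      seed = config@seed,
      configHash = .objectHash(list(config@params, config@simulation)),
      package = as.character(utils::packageVersion("taltkit"))))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    writeSimulation(simPost, file.path(outdir, "truth_postALT"))
    writeSimulation(simPre, file.path(outdir, "truth_preALT"))
    for (nm in c("preALT", "postALT")) {
      s <- if (nm == "preALT") pre else post
      h <- s$anchorHits
      .writeTsv(data.frame(readId = h$readId,
                           contig = as.character(seqnames(h)),
                           start = start(h) - 1L, end = end(h),
                           strand = as.character(strand(h)),
                           score = h$score, partnerType = h$partnerType),
                file.path(outdir, paste0("anchors_", nm, ".tsv")))
      if (length(s$regions)) {
        r <- s$regions
        names(r) <- sprintf("region%d", seq_along(r))
        rtracklayer::export(r, file.path(outdir, paste0("regions_", nm, ".bed")),
                            format = "BED")
      }
      if (!is.null(s$zygosity))
        .writeTsv(as.data.frame(s$zygosity),
                  file.path(outdir, paste0("zygosity_", nm, ".tsv")))
    }
    if (!is.null(segDf))
      .writeTsv(segDf, file.path(outdir, "cnv_segments.tsv"))
  }
  c(report, list(samples = list(preALT = pre, postALT = post), cnvProfile = cnv,
                 selectionResult = selection))
}
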
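#' @import methods
#' @importFrom stats density kmeans median pbinom pnorm pt qnorm rbinom
#'   rnorm runif sd setNames var phyper
#' @importFrom utils combn head read.delim write.table
NULL

#' Simulation configuration for a synthetic colon 5hmC cohort
#'
#' Holds every parameter of the synthetic cohort generator: genome and gene
#' geometry, hmeDIP-seq read counts and enrichment mixture, the matched
#' normal/tumour Infinium design, planted methylation-change rates per 5hmC
#' class, and the TET2/bivalency overlap structure. Defaults describe a
#' single 5 Mb chromosome carrying 300 genes with 100 narrow, 100 broad and
#' 100 unmarked promoters, sequenced to roughly 200 enrichment reads per
#' marked promoter, and a 17-pair normal/tumour array cohort.
#'
#' @slot seed integer master seed; a fixed seed yields byte-identical output.
#' @slot nChromosomes,chromLength,nGenes genome geometry.
#' @slot readLength read length in bp (reads are fixed-length intervals).
#' @slot nReadsIP,nReadsInput reads per IP / input sample.
#' @slot nDipNormal,nDipTumour number of hmeDIP samples per tissue.
#' @slot fracNarrow,fracBroad,fracUnmarked promoter profile class
#'   proportions; must sum to 1.
#' @slot fracBackground proportion of IP reads drawn from the uniform
#'   background component.
#' @slot tumourScale multiplicative reduction of all 5hmC enrichment
#'   components in tumour samples, in (0, 1].
#' @slot nPairs matched normal/tumour Infinium sample pairs.
#' @slot probesPerGene array probes simulated per promoter.
#' @slot plantedGainRate,plantedLossRate named numeric vectors
#'   \code{c(high=, low=)}: per-category probabilities that a probe carries a
#'   planted methylation gain/loss.
#' @slot effectSizeBeta mean beta shift of planted changes.
#' @slot typeIICompression compression of design-type II betas toward 0.5
#'   applied before intensity synthesis.
#' @slot intensityTotal mean M+U intensity per probe.
#' @slot betaNoiseSd truncated-Gaussian noise sd on the beta scale.
#' @slot detectionFailRate probability a probe x sample record fails
#'   detection.
#' @slot fracMethylatedLow fraction of 5hmC-low probes whose normal state is
#'   highly methylated (gives the beta density its methylated mode).
#' @slot tet2Fraction fraction of eligible 5hmC-marked promoters flagged as
#'   TET2 targets.
#' @slot bivalentGainFraction,bivalentHmcFraction target fractions of
#'   gain-prone / 5hmC-marked promoters carrying the bivalent flag.
#' @slot globalPctHmc,globalPctMc global modified-cytosine percentages
#'   (LCMS analogues) in normal tissue; tumour 5hmC is scaled by
#'   \code{tumourScale}.
#' @export
setClass("SimConfig", representation(
  seed = "integer", nChromosomes = "integer", chromLength = "integer",
  nGenes = "integer", readLength = "integer",
  nReadsIP = "integer", nReadsInput = "integer",
  nDipNormal = "integer", nDipTumour = "integer",
  fracNarrow = "numeric", fracBroad = "numeric", fracUnmarked = "numeric",
  fracBackground = "numeric", tumourScale = "numeric",
  nPairs = "integer", probesPerGene = "integer",
  plantedGainRate = "numeric", plantedLossRate = "numeric",
  effectSizeBeta = "numeric", typeIICompression = "numeric",
  intensityTotal = "numeric", betaNoiseSd = "numeric",
  detectionFailRate = "numeric", fracMethylatedLow = "numeric",
  tet2Fraction = "numeric",
  bivalentGainFraction = "numeric", bivalentHmcFraction = "numeric",
  globalPctHmc = "numeric", globalPctMc = "numeric"))

setValidity("SimConfig", function(object) {
  msg <- character()
  fr <- object@fracNarrow + object@fracBroad + object@fracUnmarked
  if (abs(fr - 1) > 1e-8)
    msg <- c(msg, "fracNarrow + fracBroad + fracUnmarked must equal 1")
  if (object@tumourScale <= 0 || object@tumourScale > 1)
    msg <- c(msg, "tumourScale must be in (0, 1]")
  rates <- c(object@plantedGainRate, object@plantedLossRate,
             object@detectionFailRate, object@fracBackground,
             object@fracMethylatedLow, object@tet2Fraction,
             object@bivalentGainFraction, object@bivalentHmcFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "all rates and fractions must lie in [0, 1]")
  if (!all(c("high", "low") %in% names(object@plantedGainRate)) ||
      !all(c("high", "low") %in% names(object@plantedLossRate)))
    msg <- c(msg, "plantedGainRate/plantedLossRate need 'high' and 'low' entries")
  if (any(object@plantedGainRate + object@plantedLossRate[names(object@plantedGainRate)] > 1))
    msg <- c(msg, "per-category gain + loss rates must not exceed 1")
  for (s in c("nChromosomes", "chromLength", "nGenes", "readLength", "nPairs",
              "probesPerGene", "nDipNormal", "nDipTumour"))
    if (slot(object, s) < 1L) msg <- c(msg, paste(s, "must be >= 1"))
  if (object@nReadsIP < 0L || object@nReadsInput < 0L)
    msg <- c(msg, "read counts must be >= 0")
  if (object@effectSizeBeta < 0 || object@effectSizeBeta > 1)
    msg <- c(msg, "effectSizeBeta must be in [0, 1]")
  if (object@typeIICompression <= 0 || object@typeIICompression > 1)
    msg <- c(msg, "typeIICompression must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a SimConfig
#'
#' @param seed integer master seed.
#' @param nChromosomes,chromLength,nGenes,readLength genome geometry.
#' @param nReadsIP,nReadsInput,nDipNormal,nDipTumour sequencing design.
#' @param fracNarrow,fracBroad,fracUnmarked promoter class proportions.
#' @param fracBackground,tumourScale enrichment mixture parameters.
#' @param nPairs,probesPerGene array design.
#' @param plantedGainRate,plantedLossRate named per-category plant rates.
#' @param effectSizeBeta,typeIICompression,intensityTotal,betaNoiseSd,detectionFailRate,fracMethylatedLow
#'   intensity model parameters.
#' @param tet2Fraction,bivalentGainFraction,bivalentHmcFraction overlap
#'   structure parameters.
#' @param globalPctHmc,globalPctMc global modification percentages.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- SimConfig(seed = 7, nGenes = 30L, chromLength = 500000L)
#' @export
SimConfig <- function(seed = 1L, nChromosomes = 1L, chromLength = 5000000L,
                      nGenes = 300L, readLength = 50L,
                      nReadsIP = 60000L, nReadsInput = 60000L,
                      nDipNormal = 5L, nDipTumour = 4L,
                      fracNarrow = 1 / 3, fracBroad = 1 / 3,
                      fracUnmarked = 1 / 3,
                      fracBackground = 0.3, tumourScale = 0.3,
                      nPairs = 17L, probesPerGene = 2L,
                      plantedGainRate = c(high = 0.05, low = 0.13),
                      plantedLossRate = c(high = 0.20, low = 0.10),
                      effectSizeBeta = 0.25, typeIICompression = 0.8,
                      intensityTotal = 2000, betaNoiseSd = 0.03,
                      detectionFailRate = 0.01, fracMethylatedLow = 0.3,
                      tet2Fraction = 0.4,
                      bivalentGainFraction = 0.65,
                      bivalentHmcFraction = 0.30,
                      globalPctHmc = 0.118, globalPctMc = 4.8) {
  new("SimConfig", seed = as.integer(seed),
      nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
      readLength = as.integer(readLength), nReadsIP = as.integer(nReadsIP),
      nReadsInput = as.integer(nReadsInput),
      nDipNormal = as.integer(nDipNormal),
      nDipTumour = as.integer(nDipTumour),
      fracNarrow = fracNarrow, fracBroad = fracBroad,
      fracUnmarked = fracUnmarked, fracBackground = fracBackground,
      tumourScale = tumourScale, nPairs = as.integer(nPairs),
      probesPerGene = as.integer(probesPerGene),
      plantedGainRate = plantedGainRate, plantedLossRate = plantedLossRate,
      effectSizeBeta = effectSizeBeta, typeIICompression = typeIICompression,
      intensityTotal = intensityTotal, betaNoiseSd = betaNoiseSd,
      detectionFailRate = detectionFailRate,
      fracMethylatedLow = fracMethylatedLow, tet2Fraction = tet2Fraction,
      bivalentGainFraction = bivalentGainFraction,
      bivalentHmcFraction = bivalentHmcFraction,
      globalPctHmc = globalPctHmc, globalPctMc = globalPctMc)
}

#' Analysis parameters of the promoter 5hmC/methylation pipeline
#'
#' Collects every tunable window, threshold and cutoff of the analysis:
#' the -1 kb/+0.5 kb promoter window, 200 bp probe windows, top-3000 locus
#' selection, 1 kb TET2 TSS flank, p < 0.01 gain/loss calls, 1,499 bp
#' maximal probe-TSS distance, and the coverage/profile geometry.
#'
#' @slot narrowUpstream,narrowDownstream promoter window extent in bp.
#' @slot probeWindow width (bp) of the window centred on each array probe
#'   in which hmeDIP reads are counted.
#' @slot topN number of 5hmC-high and 5hmC-low loci selected by ranking.
#' @slot profileN size of the narrow and broad promoter lists.
#' @slot tet2Flank TSS flank (bp) for peak-to-promoter assignment.
#' @slot alpha raw p-value threshold for gain/loss calls.
#' @slot clusterK number of joint-profile clusters.
#' @slot shoreWidth CpG island shore width in bp.
#' @slot maxProbeTssDistance maximal probe-to-TSS distance (inclusive).
#' @slot binSize coverage bin size in bp.
#' @slot metageneFlank TSS metagene half-width in bp.
#' @slot detectFloor minimal mean RPM probe-window count for a promoter to
#'   count as retaining 5hmC in tumours.
#' @slot offset stabilising intensity offset of the channel log-ratio.
#' @slot dispersion intensity dispersion used by the delta-method standard
#'   error.
#' @slot detectionAlpha detection p-value filter threshold (strict).
#' @slot uniqueRule \code{"rank"} or \code{"setdiff"} de-duplication of the
#'   narrow/broad lists.
#' @slot depletionNull \code{"binomial"} or \code{"hypergeometric"} null for
#'   the overlap depletion test.
#' @export
setClass("PipelineConfig", representation(
  narrowUpstream = "integer", narrowDownstream = "integer",
  probeWindow = "integer", topN = "integer", profileN = "integer",
  tet2Flank = "integer", alpha = "numeric", clusterK = "integer",
  shoreWidth = "integer", maxProbeTssDistance = "integer",
  binSize = "integer", metageneFlank = "integer", detectFloor = "numeric",
  offset = "numeric", dispersion = "numeric", detectionAlpha = "numeric",
  uniqueRule = "character", depletionNull = "character"))

setValidity("PipelineConfig", function(object) {
  msg <- character()
  for (s in c("narrowUpstream", "narrowDownstream", "probeWindow", "topN",
              "profileN", "tet2Flank", "clusterK", "shoreWidth",
              "maxProbeTssDistance", "binSize", "metageneFlank"))
    if (slot(object, s) <= 0L) msg <- c(msg, paste(s, "must be > 0"))
  if (object@probeWindow %% 2L != 0L) msg <- c(msg, "probeWindow must be even")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (!object@uniqueRule %in% c("rank", "setdiff"))
    msg <- c(msg, "uniqueRule must be 'rank' or 'setdiff'")
  if (!object@depletionNull %in% c("binomial", "hypergeometric"))
    msg <- c(msg, "depletionNull must be 'binomial' or 'hypergeometric'")
  if (length(msg)) msg else TRUE
})

#' Construct a PipelineConfig
#'
#' @param narrowUpstream,narrowDownstream,probeWindow,topN,profileN,tet2Flank,alpha,clusterK,shoreWidth,maxProbeTssDistance,binSize,metageneFlank,detectFloor,offset,dispersion,detectionAlpha,uniqueRule,depletionNull
#'   see the class documentation.
#' @return A validated \linkS4class{PipelineConfig}.
#' @examples
#' PipelineConfig(topN = 150L)
#' @export
PipelineConfig <- function(narrowUpstream = 1000L, narrowDownstream = 500L,
                           probeWindow = 200L, topN = 3000L,
                           profileN = 100L, tet2Flank = 1000L, alpha = 0.01,
                           clusterK = 10L, shoreWidth = 2000L,
                           maxProbeTssDistance = 1499L, binSize = 50L,
                           metageneFlank = 3000L, detectFloor = 1,
                           offset = 100, dispersion = 1,
                           detectionAlpha = 0.05, uniqueRule = "rank",
                           depletionNull = "binomial") {
  new("PipelineConfig", narrowUpstream = as.integer(narrowUpstream),
      narrowDownstream = as.integer(narrowDownstream),
      probeWindow = as.integer(probeWindow), topN = as.integer(topN),
      profileN = as.integer(profileN), tet2Flank = as.integer(tet2Flank),
      alpha = alpha, clusterK = as.integer(clusterK),
      shoreWidth = as.integer(shoreWidth),
      maxProbeTssDistance = as.integer(maxProbeTssDistance),
      binSize = as.integer(binSize),
      metageneFlank = as.integer(metageneFlank), detectFloor = detectFloor,
      offset = offset, dispersion = dispersion,
      detectionAlpha = detectionAlpha, uniqueRule = uniqueRule,
      depletionNull = depletionNull)
}

#' A set of aligned sequencing reads from one sample
#'
#' Thin container pairing the stored read intervals (a \code{GRanges}) with
#' the sample identity and the library's total mapped read count, which is
#' the per-million normalisation denominator. \code{totalMapped} may exceed
#' the number of stored reads when the stored set is a filtered subset.
#'
#' @slot sampleId sample identifier.
#' @slot reads \code{GRanges} of read intervals.
#' @slot totalMapped total mapped reads in the library.
#' @export
setClass("AlignedReadSet", representation(
  sampleId = "character", reads = "GRanges", totalMapped = "numeric"))

setValidity("AlignedReadSet", function(object) {
  if (object@totalMapped < length(object@reads))
    "totalMapped must be >= the number of stored reads"
  else TRUE
})

#' Construct an AlignedReadSet
#'
#' @param sampleId sample identifier.
#' @param reads \code{GRanges} of read intervals.
#' @param totalMapped total mapped reads (defaults to \code{length(reads)}).
#' @return An \linkS4class{AlignedReadSet}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1:5 * 100, width = 50))
#' AlignedReadSet("N01", gr)
#' @export
AlignedReadSet <- function(sampleId, reads, totalMapped = length(reads)) {
  new("AlignedReadSet", sampleId = as.character(sampleId), reads = reads,
      totalMapped = as.numeric(totalMapped))
}

#' Binned, per-million-normalised read coverage
#'
#' Per-chromosome vectors of reads-per-million coverage on a fixed bin
#' grid. Values are non-negative for raw tracks and may be negative after
#' input subtraction (subtraction is not clamped).
#'
#' @slot binSize bin width in bp.
#' @slot values named list (one numeric vector per chromosome) of RPM
#'   values.
#' @slot seqlengths named integer chromosome lengths.
#' @slot subtracted logical; \code{TRUE} after input subtraction.
#' @export
setClass("BinnedCoverage", representation(
  binSize = "integer", values = "list", seqlengths = "integer",
  subtracted = "logical"))

setValidity("BinnedCoverage", function(object) {
  msg <- character()
  if (!identical(names(object@values), names(object@seqlengths)))
    msg <- c(msg, "values and seqlengths must share chromosome names")
  nb <- ceiling(object@seqlengths / object@binSize)
  if (!all(lengths(object@values) == nb))
    msg <- c(msg, "bin vector lengths inconsistent with seqlengths/binSize")
  if (!object@subtracted && any(unlist(object@values, use.names = FALSE) < 0))
    msg <- c(msg, "raw (unsubtracted) coverage must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A synthetic 5hmC cohort with planted ground truth
#'
#' The full output of \code{\link{simulateCohort}}: genome sequence, gene
#' models, hmeDIP read sets, Infinium-style probe manifest and intensity
#' table, ChIP peak set, bivalent gene list, and the truth sidecar used by
#' recovery tests.
#'
#' @slot genome \code{DNAStringSet} chromosome sequences.
#' @slot genes \code{GRanges} gene models with \code{gene_id}, \code{tss},
#'   \code{tts} metadata.
#' @slot probes \code{GRanges} probe manifest (width-1 positions with
#'   design type and QC flags).
#' @slot readSets named list of \linkS4class{AlignedReadSet}.
#' @slot intensities long-format data.frame (probe_id, sample_id, M, U,
#'   detection_p).
#' @slot pairing data.frame (normal_id, tumour_id).
#' @slot peaks \code{GRanges} TET2-like peak set.
#' @slot bivalentGenes character vector of bivalent gene ids.
#' @slot truth list of planted truth (promoter classes, per-probe normal
#'   and tumour betas, planted change labels, TET2/bivalent flags).
#' @slot config the generating \linkS4class{SimConfig}.
#' @export
setClass("HmcCohort", representation(
  genome = "DNAStringSet", genes = "GRanges", probes = "GRanges",
  readSets = "list", intensities = "data.frame", pairing = "data.frame",
  peaks = "GRanges", bivalentGenes = "character", truth = "list",
  config = "SimConfig"))

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChromosomes, "chromosome(s) x",
      object@chromLength, "bp,", object@nGenes, "genes\n")
  cat("  promoter classes narrow/broad/unmarked:",
      sprintf("%.2f/%.2f/%.2f", object@fracNarrow, object@fracBroad,
              object@fracUnmarked), "\n")
  cat("  hmeDIP:", object@nDipNormal, "normal +", object@nDipTumour,
      "tumour IP samples,", object@nReadsIP, "reads each; tumour scale",
      object@tumourScale, "\n")
  cat("  Infinium:", object@nPairs, "matched pairs,",
      object@probesPerGene, "probes/gene; planted gain/loss (high):",
      object@plantedGainRate[["high"]], "/",
      object@plantedLossRate[["high"]], " (low):",
      object@plantedGainRate[["low"]], "/",
      object@plantedLossRate[["low"]], "\n")
  cat("  seed:", object@seed, "\n")
})

setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig: promoter window -", object@narrowUpstream, "/+",
      object@narrowDownstream, "bp; probe window", object@probeWindow,
      "bp; topN", object@topN, "; alpha", object@alpha, "\n")
})

setMethod("show", "AlignedReadSet", function(object) {
  cat("AlignedReadSet", object@sampleId, ":", length(object@reads),
      "stored reads,", object@totalMapped, "total mapped\n")
})

setMethod("show", "BinnedCoverage", function(object) {
  cat("BinnedCoverage:", length(object@values), "chromosome(s), bin",
      object@binSize, "bp",
      if (object@subtracted) "(input-subtracted)" else "(raw RPM)", "\n")
})

setMethod("show", "HmcCohort", function(object) {
  cat("HmcCohort:", length(object@genome), "chromosome(s),",
      length(object@genes), "genes,", length(object@probes), "probes,",
      length(object@readSets), "read sets,", length(object@peaks),
      "peaks\n")
})
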
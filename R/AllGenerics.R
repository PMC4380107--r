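#' Accessors for package classes
#'
#' Small accessor generics for the container classes: sample identity, read
#' intervals and mapped totals of an \linkS4class{AlignedReadSet}; bin size
#' and per-chromosome values of a \linkS4class{BinnedCoverage}; and the
#' components of an \linkS4class{HmcCohort}.
#'
#' @param x an object of the documented class.
#' @param chrom optional chromosome name to extract a single vector.
#' @return The corresponding slot (or element).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("readIntervals", function(x) standardGeneric("readIntervals"))
#' @rdname accessors
#' @export
setGeneric("totalMapped", function(x) standardGeneric("totalMapped"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("coverageValues", function(x, chrom) standardGeneric("coverageValues"))
#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setGeneric("probeManifest", function(x) standardGeneric("probeManifest"))
#' @rdname accessors
#' @export
setGeneric("readSets", function(x) standardGeneric("readSets"))
#' @rdname accessors
#' @export
setGeneric("intensityTable", function(x) standardGeneric("intensityTable"))
#' @rdname accessors
#' @export
setGeneric("samplePairing", function(x) standardGeneric("samplePairing"))
#' @rdname accessors
#' @export
setGeneric("peakSet", function(x) standardGeneric("peakSet"))
#' @rdname accessors
#' @export
setGeneric("bivalentGenes", function(x) standardGeneric("bivalentGenes"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("simConfig", function(x) standardGeneric("simConfig"))

#' @rdname accessors
#' @export
setMethod("sampleId", "AlignedReadSet", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("readIntervals", "AlignedReadSet", function(x) x@reads)
#' @rdname accessors
#' @export
setMethod("totalMapped", "AlignedReadSet", function(x) x@totalMapped)
#' @rdname accessors
#' @export
setMethod("binSize", "BinnedCoverage", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("coverageValues", "BinnedCoverage", function(x, chrom) {
  if (missing(chrom)) x@values else x@values[[chrom]]
})
#' @rdname accessors
#' @export
setMethod("genomeSeq", "HmcCohort", function(x) x@genome)
#' @rdname accessors
#' @export
setMethod("geneModels", "HmcCohort", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("probeManifest", "HmcCohort", function(x) x@probes)
#' @rdname accessors
#' @export
setMethod("readSets", "HmcCohort", function(x) x@readSets)
#' @rdname accessors
#' @export
setMethod("intensityTable", "HmcCohort", function(x) x@intensities)
#' @rdname accessors
#' @export
setMethod("samplePairing", "HmcCohort", function(x) x@pairing)
#' @rdname accessors
#' @export
setMethod("peakSet", "HmcCohort", function(x) x@peaks)
#' @rdname accessors
#' @export
setMethod("bivalentGenes", "HmcCohort", function(x) x@bivalentGenes)
#' @rdname accessors
#' @export
setMethod("cohortTruth", "HmcCohort", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("simConfig", "HmcCohort", function(x) x@config)
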
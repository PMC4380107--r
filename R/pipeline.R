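## Run an expression as a named pipeline stage: any error aborts with the
## failing stage named.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

## Elementwise mean of a list of BinnedCoverage tracks on one grid.
.averageCoverage <- function(tracks) {
  vals <- tracks[[1]]@values
  for (t in tracks[-1]) vals <- Map(`+`, vals, t@values)
  vals <- lapply(vals, function(v) v / length(tracks))
  new("BinnedCoverage", binSize = tracks[[1]]@binSize, values = vals,
      seqlengths = tracks[[1]]@seqlengths,
      subtracted = any(vapply(tracks, function(t) t@subtracted, logical(1))))
}

## Long intensity table -> probe x sample matrix of one column.
.intensityMatrix <- function(intens, col) {
  probes <- sort(unique(intens$probe_id))
  samples <- sort(unique(intens$sample_id))
  m <- matrix(NA_real_, length(probes), length(samples),
              dimnames = list(probes, samples))
  m[cbind(match(intens$probe_id, probes),
          match(intens$sample_id, samples))] <- intens[[col]]
  m
}

## Merge several AlignedReadSets into one (totals summed).
.mergeReadSets <- function(readSets, id = "pooled") {
  gr <- do.call(c, unname(lapply(readSets, readIntervals)))
  AlignedReadSet(id, gr, totalMapped = sum(vapply(readSets, totalMapped,
                                                  numeric(1))))
}

## Balanced accuracy of predicted narrow/broad/unmarked labels vs truth.
.balancedAccuracy <- function(predicted, truthClass) {
  classes <- c("narrow", "broad", "unmarked")
  rec <- vapply(classes, function(cl) {
    idx <- truthClass == cl
    if (!any(idx)) return(NA_real_)
    mean(predicted[idx] == cl)
  }, numeric(1))
  mean(rec, na.rm = TRUE)
}

#' Predicted profile labels from a narrow/broad selection
#'
#' Converts the output of \code{\link{selectTopProfiles}} into a named
#' label vector (narrow / broad / unmarked) over all genes.
#'
#' @param selection output of \code{\link{selectTopProfiles}}.
#' @param geneIds all gene ids.
#' @return named character vector.
#' @export
profileLabels <- function(selection, geneIds) {
  lab <- setNames(rep("unmarked", length(geneIds)), geneIds)
  lab[selection$narrow] <- "narrow"
  lab[selection$broad] <- "broad"
  lab
}

#' Run the full 5hmC/methylation integration pipeline
#'
#' Executes the stages in order on a synthetic cohort (or an on-disk input
#' bundle): promoter annotation (CpG classes, islands), hmeDIP coverage
#' (RPM normalisation, input subtraction, metagene, feature distribution),
#' promoter profiling (narrow/broad ranking, joint profile clustering),
#' Infinium processing (filtering, peak-based type I/II correction,
#' weighted moderated differential methylation) and the integration
#' statistics (5hmC-high/low cross-tabulation, TET2 overlap depletion,
#' bivalency Venn analysis, persistent-5hmC cross-tabulation, and the
#' hmC share of the bisulfite signal). Returns the summary as a list and
#' optionally writes it as deterministic JSON.
#'
#' The configured \code{topN} is clamped to half the number of retained
#' probes (with a message) so that paper-scale defaults run on small
#' synthetic cohorts.
#'
#' @param x a \linkS4class{SimConfig} (cohort is simulated), an
#'   \linkS4class{HmcCohort}, or a directory written by
#'   \code{\link{writeCohort}}.
#' @param pconfig a \linkS4class{PipelineConfig}.
#' @param summaryJson optional path; the summary is written there as JSON.
#' @param islands passed to \code{\link{simulateCohort}} when \code{x} is
#'   a config.
#' @return a named list of all computed statistics (invisibly identical to
#'   the JSON content).
#' @export
runPipeline <- function(x, pconfig = PipelineConfig(), summaryJson = NULL,
                        islands = TRUE) {
  cohort <- .stage("input", {
    if (is(x, "SimConfig")) simulateCohort(x, islands = islands)
    else if (is(x, "HmcCohort")) x
    else if (is.character(x) && length(x) == 1L) readCohort(x)
    else stop("x must be a SimConfig, HmcCohort or bundle directory")
  })
  cfg <- simConfig(cohort)
  genes <- geneModels(cohort)
  gid <- genes$gene_id
  seqlens <- seqlengths(genes)

  ## ---- annotation ----
  ann <- .stage("annotation", {
    ctx <- promoterContext(genomeSeq(cohort), genes)
    cpgClass <- classifyPromoterCpG(ctx)
    islandsByChr <- lapply(names(genomeSeq(cohort)), function(chr)
      findCpGIslands(genomeSeq(cohort)[[chr]], chrom = chr))
    islandsGR <- do.call(c, islandsByChr)
    probes <- assignProbesToPromoters(probeManifest(cohort), genes,
                                      pconfig@maxProbeTssDistance)
    list(cpgClass = setNames(as.character(cpgClass), gid),
         islands = islandsGR, probes = probes)
  })

  ## ---- coverage ----
  cov <- .stage("coverage", {
    rs <- readSets(cohort)
    normIds <- grep("^hmN", names(rs), value = TRUE)
    tumIds <- grep("^hmT", names(rs), value = TRUE)
    inputN <- normalizedCoverage(rs[["inputN"]], seqlens, pconfig@binSize)
    inputT <- normalizedCoverage(rs[["inputT"]], seqlens, pconfig@binSize)
    netN <- .averageCoverage(lapply(normIds, function(id)
      inputSubtract(normalizedCoverage(rs[[id]], seqlens, pconfig@binSize),
                    inputN)))
    netT <- .averageCoverage(lapply(tumIds, function(id)
      inputSubtract(normalizedCoverage(rs[[id]], seqlens, pconfig@binSize),
                    inputT)))
    pooledN <- .mergeReadSets(rs[normIds], "pooledNormal")
    meta <- tssMetagene(netN, genes, pconfig@metageneFlank)
    featDist <- featureDistribution(pooledN, genes,
                                    pconfig@narrowUpstream,
                                    pconfig@narrowDownstream)
    list(netNormal = netN, netTumour = netT, metagene = meta,
         featureDistribution = featDist, normIds = normIds,
         tumIds = tumIds)
  })

  ## ---- profiles ----
  prof <- .stage("profiles", {
    rs <- readSets(cohort)
    scores <- scorePromoters(rs[cov$normIds], genes,
                             pconfig@narrowUpstream,
                             pconfig@narrowDownstream)
    sel <- selectTopProfiles(scores, min(pconfig@profileN, nrow(scores)),
                             rule = pconfig@uniqueRule)
    labels <- profileLabels(sel, gid)
    ## joint clustering: 5hmC net coverage vs an array-derived 5mC track
    m5hmc <- profileMatrix(cov$netNormal, genes, upstream = 3000L,
                           downstream = 20000L)
    m5mc <- tryCatch({
      betaN <- .intensityMatrix(intensityTable(cohort), "M") /
        (.intensityMatrix(intensityTable(cohort), "M") +
           .intensityMatrix(intensityTable(cohort), "U"))
      nm <- grep("^N", colnames(betaN), value = TRUE)
      probeBeta <- rowMeans(betaN[, nm, drop = FALSE], na.rm = TRUE)
      .probeBetaMatrix(ann$probes, probeBeta, genes, rownames(m5hmc),
                       cov$netNormal@binSize, 3000L, 20000L)
    }, error = function(e) NULL)
    clust <- if (!is.null(m5mc))
      clusterJointProfiles(m5hmc, m5mc, k = min(pconfig@clusterK,
                                                nrow(m5hmc)),
                           seed = cfg@seed)
    else NULL
    ## island/shore meta-profile, islands oriented by host promoter strand
    prom <- promoterWindow(genes, pconfig@narrowUpstream,
                           pconfig@narrowDownstream)
    hit <- findOverlaps(ann$islands, prom, ignore.strand = TRUE)
    promIslands <- ann$islands[queryHits(hit)]
    strand(promIslands) <- strand(prom)[subjectHits(hit)]
    shore <- if (length(promIslands))
      islandShoreProfile(cov$netNormal, promIslands,
                         shoreWidth = pconfig@shoreWidth)
    else NULL
    list(scores = scores, selection = sel, labels = labels,
         clusters = clust, shoreProfile = shore)
  })

  ## ---- arrays ----
  arr <- .stage("arrays", {
    intens <- intensityTable(cohort)
    kept <- filterProbes(intens, ann$probes, pconfig@detectionAlpha)
    keptProbes <- sort(unique(kept$probe_id))
    M <- .intensityMatrix(kept, "M")
    U <- .intensityMatrix(kept, "U")
    betas <- betaValue(M, U)
    design <- ann$probes$design_type[match(rownames(betas),
                                           ann$probes$probe_id)]
    betasCorr <- tryCatch(peakBasedCorrection(betas, design),
                          error = function(e) {
                            message("peak-based correction skipped: ",
                                    conditionMessage(e))
                            betas
                          })
    lr <- muLogRatio(as.vector(M), as.vector(U), pconfig@offset,
                     pconfig@dispersion)
    lrMat <- matrix(lr$log_ratio, nrow(M), ncol(M), dimnames = dimnames(M))
    seMat <- matrix(lr$se, nrow(M), ncol(M), dimnames = dimnames(M))
    dm <- weightedDiffMeth(lrMat, seMat, samplePairing(cohort),
                           betas = betasCorr, alpha = pconfig@alpha)
    list(betas = betasCorr, diffmeth = dm, keptProbes = keptProbes)
  })

  ## ---- integration ----
  intg <- .stage("integration", {
    rs <- readSets(cohort)
    probesKept <- ann$probes[ann$probes$probe_id %in% arr$keptProbes]
    cntN <- countReadsInProbeWindows(rs[cov$normIds], probesKept,
                                     pconfig@probeWindow)
    cntT <- countReadsInProbeWindows(rs[cov$tumIds], probesKept,
                                     pconfig@probeWindow)
    ## the default topN targets a 27k-style array where 3,000 loci are
    ## ~11% of the platform; on smaller cohorts keep the same tail
    ## fraction so "high" and "low" stay genuine distribution tails
    topN <- pconfig@topN
    if (2L * topN > nrow(cntN)) {
      topN <- max(1L, as.integer(round(0.11 * nrow(cntN))))
      message("topN rescaled to ", topN,
              " (11% tail of ", nrow(cntN), " retained probes)")
    }
    hl <- selectHighLowLoci(cntN, topN)
    ctHigh <- crosstabMethylation(hl$high, arr$diffmeth)
    ctLow <- crosstabMethylation(hl$low, arr$diffmeth)
    probeGene <- setNames(probesKept$gene_id, probesKept$probe_id)
    promState <- promoterMethylationState(arr$diffmeth, probeGene)
    gainProm <- names(promState)[promState == "gain"]
    lossProm <- names(promState)[promState == "loss"]
    tet2 <- tet2TargetPromoters(peakSet(cohort), genes, pconfig@tet2Flank)
    depl <- overlapDepletionTest(gainProm, tet2, gid,
                                 null = pconfig@depletionNull)
    hmcProm <- union(prof$selection$narrow, prof$selection$broad)
    venn <- vennThreeWay(hmcProm, bivalentGenes(cohort), gainProm, gid)
    ## tumour probe-window scores aggregated to promoters
    gKey <- probeGene[cntT$probe_id]
    aggT <- tapply(cntT$rpm_mean, gKey, sum)
    tumourScores <- data.frame(gene_id = names(aggT),
                               rpm_mean = as.numeric(aggT))
    persist <- persistentHmcCrosstab(tumourScores, promState,
                                     pconfig@detectFloor)
    hmcFracN <- hmcFractionOfBisulfiteSignal(cfg@globalPctHmc,
                                             cfg@globalPctMc)
    hmcFracT <- hmcFractionOfBisulfiteSignal(
      cfg@globalPctHmc * cfg@tumourScale, cfg@globalPctMc)
    list(countsNormal = cntN, countsTumour = cntT, highLow = hl,
         crosstabHigh = ctHigh, crosstabLow = ctLow,
         promoterState = promState, gainPromoters = gainProm,
         lossPromoters = lossProm, tet2Targets = tet2, depletion = depl,
         venn = venn, persistent = persist,
         hmcFractionNormal = hmcFracN, hmcFractionTumour = hmcFracT,
         topNUsed = topN)
  })

  truth <- cohortTruth(cohort)
  balAcc <- if (!is.null(truth$promoterClass))
    .balancedAccuracy(prof$labels[names(truth$promoterClass)],
                      truth$promoterClass)
  else NA_real_

  summary <- list(
    schema_version = "1.0",
    seed = cfg@seed,
    n_genes = length(gid),
    n_probes_retained = length(arr$keptProbes),
    top_n_used = intg$topNUsed,
    profile_n = min(pconfig@profileN, length(gid)),
    n_narrow = length(prof$selection$narrow),
    n_broad = length(prof$selection$broad),
    profile_balanced_accuracy = balAcc,
    cpg_class_counts = as.list(table(ann$cpgClass)),
    feature_distribution = as.list(cov$featureDistribution),
    crosstab_high = intg$crosstabHigh,
    crosstab_low = intg$crosstabLow,
    n_gain_promoters = length(intg$gainPromoters),
    n_loss_promoters = length(intg$lossPromoters),
    n_tet2_targets = length(intg$tet2Targets),
    tet2_overlap = intg$depletion,
    venn = list(counts = as.list(intg$venn$counts),
                frac_gain_bivalent = intg$venn$frac_gain_bivalent,
                frac_hmc_bivalent = intg$venn$frac_hmc_bivalent),
    persistent_5hmc = intg$persistent[c("n_persistent", "n_gain",
                                        "n_loss", "frac_gain",
                                        "frac_loss")],
    hmc_fraction_of_bisulfite = list(normal = intg$hmcFractionNormal,
                                     tumour = intg$hmcFractionTumour),
    cluster_sizes = if (!is.null(prof$clusters))
      as.list(prof$clusters$sizes) else NULL)

  if (!is.null(summaryJson)) {
    dir.create(dirname(summaryJson), recursive = TRUE, showWarnings = FALSE)
    writeLines(toJSON(summary, auto_unbox = TRUE, digits = 10,
                      pretty = TRUE, null = "null"), summaryJson)
  }
  invisible(list(summary = summary, annotation = ann, coverage = cov,
                 profiles = prof, arrays = arr, integration = intg,
                 cohort = cohort))
}

## Array-derived 5mC surrogate profile matrix: mean normal beta of probes
## dropped into the promoter-anchored bin grid (zeros elsewhere).
.probeBetaMatrix <- function(probes, probeBeta, genes, keepIds, binSize,
                             upstream, downstream) {
  nUp <- as.integer(upstream / binSize)
  nDn <- as.integer(downstream / binSize)
  nc <- nUp + nDn
  m <- matrix(0, length(keepIds), nc, dimnames = list(keepIds, NULL))
  tssOf <- setNames(genes$tss, genes$gene_id)
  minusOf <- setNames(as.character(strand(genes)) == "-", genes$gene_id)
  pg <- probes$gene_id
  for (i in seq_along(probes)) {
    g <- pg[i]
    if (is.na(g) || !(g %in% keepIds)) next
    d <- start(probes)[i] - tssOf[g]
    if (minusOf[g]) d <- -d
    col <- nUp + 1L + as.integer(floor(d / binSize))
    if (col >= 1L && col <= nc) {
      b <- probeBeta[probes$probe_id[i]]
      if (is.finite(b)) m[g, col] <- b
    }
  }
  m
}
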
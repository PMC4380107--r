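## Truncated-normal sampling via inverse-CDF; exact, vectorised,
## deterministic under set.seed.
.rtrunc <- function(n, mean, sd, lo, hi) {
  if (length(mean) == 1L) mean <- rep(mean, n)
  if (length(sd) == 1L) sd <- rep(sd, n)
  plo <- pnorm(lo, mean, sd); phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

## Sample a base vector with a target CpG regime: iid draw from baseProbs
## (A, C, G, T), then break a fraction of CpG dinucleotides (G -> A) to
## deplete the observed/expected ratio.
.sampleRegime <- function(n, baseProbs, cpgBreak) {
  x <- sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = baseProbs)
  if (cpgBreak > 0 && n >= 2L) {
    cg <- which(x[-n] == "C" & x[-1] == "G")
    if (length(cg)) {
      brk <- cg[runif(length(cg)) < cpgBreak]
      x[brk + 1L] <- "A"
    }
  }
  x
}

#' Generate a synthetic genome with gene models and CpG regimes
#'
#' Builds chromosome sequences from a two-regime dinucleotide sampler:
#' a CpG-depleted background (85 percent of CpG dinucleotides broken,
#' observed/expected around 0.15) and CpG-rich segments planted at the
#' promoters of 5hmC-marked genes - a high-CpG regime (GC 0.6,
#' obs/exp near 1) at broad-profile promoters and an intermediate regime
#' at narrow-profile promoters, echoing the association of broad profiles
#' with HCP and narrow with ICP promoters. Non-overlapping gene models are
#' placed on both strands with recorded TSS/TTS; promoter profile classes
#' (narrow/broad/unmarked) are drawn at the configured proportions and
#' recorded as ground truth.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param islands logical; \code{FALSE} disables the CpG-rich regimes
#'   (every promoter is then background, hence LCP).
#' @param seed RNG seed (defaults to \code{config@seed}).
#' @return list with \code{genome} (\code{DNAStringSet}), \code{genes}
#'   (\code{GRanges} with \code{gene_id}, \code{tss}, \code{tts}),
#'   \code{truth} (promoter classes, island regimes, planted island
#'   \code{GRanges}).
#' @export
simulateGenome <- function(config, islands = TRUE, seed = config@seed) {
  set.seed(seed)
  nChr <- config@nChromosomes
  L <- config@chromLength
  perChr <- rep(config@nGenes %/% nChr, nChr)
  extra <- config@nGenes %% nChr
  if (extra > 0) perChr[seq_len(extra)] <- perChr[seq_len(extra)] + 1L
  margin <- 5000L
  chromNames <- paste0("chr", seq_len(nChr))
  geneRows <- list()
  gi <- 0L
  for (ci in seq_len(nChr)) {
    cursor <- margin + 1L
    for (k in seq_len(perChr[ci])) {
      w <- as.integer(round(runif(1, 2000, 8000)))
      gap <- as.integer(round(runif(1, 2500, 4500)))
      if (cursor + w > L - margin)
        stop("chromLength too small to place ", config@nGenes,
             " non-overlapping genes")
      gi <- gi + 1L
      geneRows[[gi]] <- data.frame(
        chrom = chromNames[ci], start = cursor, end = cursor + w - 1L,
        strand = sample(c("+", "-"), 1L))
      cursor <- cursor + w + gap
    }
  }
  gdf <- do.call(rbind, geneRows)
  gdf$gene_id <- sprintf("G%04d", seq_len(nrow(gdf)))
  gdf$tss <- ifelse(gdf$strand == "-", gdf$end, gdf$start)
  gdf$tts <- ifelse(gdf$strand == "-", gdf$start, gdf$end)
  ## promoter profile classes at configured proportions
  n <- nrow(gdf)
  nNarrow <- round(config@fracNarrow * n)
  nBroad <- round(config@fracBroad * n)
  cls <- sample(rep(c("narrow", "broad", "unmarked"),
                    c(nNarrow, nBroad, n - nNarrow - nBroad)))
  ## sequences: background regime, then island regimes at marked promoters
  seqs <- character(nChr)
  islandRows <- list()
  for (ci in seq_len(nChr)) {
    ## background break rate chosen so that no 500 bp window of a plain
    ## background promoter reaches the ICP obs/exp threshold (the
    ## disabled-island contract: every promoter classifies LCP)
    x <- .sampleRegime(L, c(0.30, 0.20, 0.20, 0.30), cpgBreak = 0.92)
    if (islands) {
      sel <- which(gdf$chrom == chromNames[ci] & cls != "unmarked")
      for (i in sel) {
        len <- if (cls[i] == "broad") 1200L else 700L
        s <- max(1L, gdf$tss[i] - len %/% 2L)
        e <- min(L, s + len - 1L)
        if (cls[i] == "broad")
          x[s:e] <- .sampleRegime(e - s + 1L, c(0.20, 0.30, 0.30, 0.20), 0)
        else
          x[s:e] <- .sampleRegime(e - s + 1L, c(0.28, 0.22, 0.22, 0.28), 0.40)
        islandRows[[length(islandRows) + 1L]] <- data.frame(
          chrom = chromNames[ci], start = s, end = e,
          regime = if (cls[i] == "broad") "hcp" else "icp",
          gene_id = gdf$gene_id[i])
      }
    }
    seqs[ci] <- paste(x, collapse = "")
  }
  genome <- DNAStringSet(seqs)
  names(genome) <- chromNames
  genes <- GRanges(gdf$chrom, IRanges(gdf$start, gdf$end),
                   strand = gdf$strand, gene_id = gdf$gene_id,
                   tss = gdf$tss, tts = gdf$tts)
  seqlengths(genes) <- setNames(rep(L, nChr), chromNames)
  planted <- if (length(islandRows)) {
    idf <- do.call(rbind, islandRows)
    GRanges(idf$chrom, IRanges(idf$start, idf$end), regime = idf$regime,
            gene_id = idf$gene_id)
  } else GRanges()
  list(genome = genome, genes = genes,
       truth = list(promoterClass = setNames(cls, gdf$gene_id),
                    islandRegime = setNames(
                      ifelse(cls == "broad", "hcp",
                             ifelse(cls == "narrow", "icp", "none")),
                      gdf$gene_id),
                    plantedIslands = planted))
}

#' Generate hmeDIP-seq reads for one sample
#'
#' Read midpoints are drawn from a mixture of a uniform genomic background
#' and per-promoter enrichment kernels. Narrow promoters contribute two
#' flanking Gaussian components inside the -1 kb/+0.5 kb window with a
#' depleted TSS bin (no midpoints within 60 bp of the TSS); broad
#' promoters contribute a uniform gene-body component. Tumour samples
#' scale every enrichment weight by \code{tumourScale}, returning the
#' displaced mass to the background (the antibody pulls down a fixed
#' library amount), so the promoter-window RPM ratio between tumour and
#' normal equals the scale factor in expectation. Input samples are
#' background-only. Reads are fixed-length intervals; the emitted count
#' equals the requested count exactly.
#'
#' @param genes \code{GRanges} gene models.
#' @param truth truth list from \code{\link{simulateGenome}}.
#' @param sampleKind \code{"normal"}, \code{"tumour"} or \code{"input"}.
#' @param config a \linkS4class{SimConfig}.
#' @param sampleId sample identifier.
#' @param seed RNG seed.
#' @return an \linkS4class{AlignedReadSet} (empty with
#'   \code{totalMapped = 0} when zero reads are requested).
#' @export
simulateDipReads <- function(genes, truth, sampleKind, config, sampleId,
                             seed = config@seed) {
  sampleKind <- match.arg(sampleKind, c("normal", "tumour", "input"))
  set.seed(seed)
  L <- config@chromLength
  rl <- config@readLength
  chroms <- names(seqlengths(genes))
  seqlens <- seqlengths(genes)
  nReads <- if (sampleKind == "input") config@nReadsInput else
    config@nReadsIP
  if (nReads == 0L) {
    gr <- GRanges(seqlengths = seqlens)
    return(AlignedReadSet(sampleId, gr, totalMapped = 0))
  }
  cls <- truth$promoterClass[genes$gene_id]
  marked <- which(cls != "unmarked")
  b <- config@fracBackground
  s <- if (sampleKind == "tumour") config@tumourScale else 1
  if (sampleKind == "input" || !length(marked)) {
    wBg <- 1; wProm <- numeric(0); marked <- integer(0)
  } else {
    wProm <- rep(s * (1 - b) / length(marked), length(marked))
    wBg <- 1 - sum(wProm)
  }
  comp <- sample.int(length(marked) + 1L, nReads, replace = TRUE,
                     prob = c(wBg, wProm)) - 1L
  mids <- integer(nReads)
  chromOf <- character(nReads)
  isBg <- comp == 0L
  nBg <- sum(isBg)
  if (nBg) {
    ci <- sample.int(length(chroms), nBg, replace = TRUE,
                     prob = seqlens / sum(seqlens))
    chromOf[isBg] <- chroms[ci]
    mids[isBg] <- as.integer(ceiling(runif(nBg) * seqlens[ci]))
  }
  if (any(!isBg)) {
    gidx <- marked[comp[!isBg]]
    tss <- genes$tss[gidx]
    minus <- as.character(strand(genes))[gidx] == "-"
    kind <- cls[gidx]
    nE <- length(gidx)
    off <- numeric(nE)
    isNarrow <- kind == "narrow"
    if (any(isNarrow)) {
      k <- sum(isNarrow)
      upC <- runif(k) < 0.6
      o <- numeric(k)
      o[upC] <- .rtrunc(sum(upC), -450, 150, -1000, -60)
      o[!upC] <- .rtrunc(sum(!upC), 220, 120, 60, 480)
      off[isNarrow] <- o
    }
    if (any(!isNarrow)) {
      gw <- width(genes)[gidx[!isNarrow]]
      off[!isNarrow] <- runif(sum(!isNarrow)) * (gw - 1)
    }
    pos <- ifelse(minus, tss - round(off), tss + round(off))
    chromOf[!isBg] <- as.character(seqnames(genes))[gidx]
    mids[!isBg] <- as.integer(pmin(pmax(pos, 1L), L))
  }
  startPos <- pmin(pmax(mids - rl %/% 2L, 1L), L - rl + 1L)
  gr <- GRanges(chromOf, IRanges(startPos, width = rl),
                strand = sample(c("+", "-"), nReads, replace = TRUE))
  seqlengths(gr) <- seqlens
  gr <- GenomicRanges::sort(gr, ignore.strand = TRUE)
  AlignedReadSet(sampleId, gr, totalMapped = nReads)
}

#' Generate Infinium-style probe manifest and intensity tables
#'
#' Places \code{probesPerGene} probes within 800 bp of each TSS and draws
#' per-probe normal-tissue betas by 5hmC class: probes at 5hmC-marked
#' promoters get intermediate betas (mean 0.40), probes at unmarked
#' promoters a 70/30 mixture of low (mean 0.12) and high (mean 0.85)
#' betas. Planted methylation changes shift the tumour beta by plus/minus
#' \code{effectSizeBeta} at the configured per-category rates (clipped to
#' [0.01, 0.99]; clip counts are recorded in the truth). Intensities are
#' synthesised as \code{M = round(T * beta_obs)}, \code{U = T - M} with
#' design-type II betas first compressed toward 0.5 by
#' \code{typeIICompression}; detection failures are assigned independently
#' per probe x sample.
#'
#' @param genes \code{GRanges} gene models.
#' @param truth truth list (promoter classes).
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed.
#' @return list with \code{probes} (\code{GRanges} manifest),
#'   \code{intensities} (long data.frame), \code{pairing} and
#'   \code{truth} (per-probe category, normal/tumour betas, planted
#'   labels, clip count).
#' @export
simulateInfinium <- function(genes, truth, config, seed = config@seed) {
  set.seed(seed)
  ppg <- config@probesPerGene
  nP <- length(genes) * ppg
  gidx <- rep(seq_along(genes), each = ppg)
  offset <- sample(c(-800:-20, 20:800), nP, replace = TRUE)
  minus <- as.character(strand(genes))[gidx] == "-"
  pos <- ifelse(minus, genes$tss[gidx] - offset, genes$tss[gidx] + offset)
  pos <- pmin(pmax(pos, 1L), seqlengths(genes)[
    as.character(seqnames(genes))[gidx]])
  probeId <- sprintf("cg%05d", seq_len(nP))
  design <- sample(c("I", "II"), nP, replace = TRUE)
  probes <- GRanges(as.character(seqnames(genes))[gidx],
                    IRanges(as.integer(pos), width = 1L),
                    probe_id = probeId,
                    design_type = design,
                    cross_reactive = runif(nP) < 0.02,
                    snp = runif(nP) < 0.02,
                    sex_chrom = runif(nP) < 0.02,
                    true_gene = genes$gene_id[gidx])
  seqlengths(probes) <- seqlengths(genes)
  cls <- truth$promoterClass[genes$gene_id[gidx]]
  ## a probe is a 5hmC-high locus when its 200 bp window can catch the
  ## host promoter's enrichment: the narrow kernels live in
  ## [-1000, -60] u [60, 480] around the TSS and the broad component in
  ## the gene body, so upstream probes of broad genes are locally 5hmC-low
  highLocal <- (cls == "narrow" & offset >= -800 & offset <= 580) |
    (cls == "broad" & offset >= -100)
  category <- ifelse(highLocal, "high", "low")
  normalBeta <- numeric(nP)
  isHigh <- category == "high"
  normalBeta[isHigh] <- .rtrunc(sum(isHigh), 0.40, 0.10, 0.05, 0.95)
  isMeth <- !isHigh & runif(nP) < config@fracMethylatedLow
  isLow <- !isHigh & !isMeth
  normalBeta[isMeth] <- .rtrunc(sum(isMeth), 0.85, 0.06, 0.50, 0.98)
  normalBeta[isLow] <- .rtrunc(sum(isLow), 0.12, 0.06, 0.02, 0.50)
  u <- runif(nP)
  gRate <- config@plantedGainRate[category]
  lRate <- config@plantedLossRate[category]
  planted <- ifelse(u < gRate, "gain",
                    ifelse(u < gRate + lRate, "loss", "none"))
  shift <- ifelse(planted == "gain", config@effectSizeBeta,
                  ifelse(planted == "loss", -config@effectSizeBeta, 0))
  rawTumour <- normalBeta + shift
  tumourBeta <- pmin(pmax(rawTumour, 0.01), 0.99)
  nClipped <- sum(rawTumour != tumourBeta)
  ## long-format intensities for nPairs matched normal/tumour samples
  nid <- sprintf("N%02d", seq_len(config@nPairs))
  tid <- sprintf("T%02d", seq_len(config@nPairs))
  sampleIds <- c(nid, tid)
  nS <- length(sampleIds)
  probeRep <- rep(probeId, nS)
  sampleRep <- rep(sampleIds, each = nP)
  isTumour <- rep(c(rep(FALSE, config@nPairs), rep(TRUE, config@nPairs)),
                  each = nP)
  trueB <- ifelse(isTumour, rep(tumourBeta, nS), rep(normalBeta, nS))
  noisyB <- if (config@betaNoiseSd > 0)
    .rtrunc(nP * nS, trueB, config@betaNoiseSd, 0, 1) else trueB
  isII <- rep(design == "II", nS)
  obsB <- ifelse(isII, 0.5 + (noisyB - 0.5) * config@typeIICompression,
                 noisyB)
  total <- pmax(100, round(rnorm(nP * nS, config@intensityTotal,
                                 0.05 * config@intensityTotal)))
  M <- round(total * obsB)
  U <- total - M
  fail <- runif(nP * nS) < config@detectionFailRate
  detP <- ifelse(fail, runif(nP * nS, 0.05, 1), runif(nP * nS, 0, 0.049))
  intens <- data.frame(probe_id = probeRep, sample_id = sampleRep,
                       M = M, U = U, detection_p = detP)
  list(probes = probes, intensities = intens,
       pairing = data.frame(normal_id = nid, tumour_id = tid),
       truth = list(probeCategory = setNames(category, probeId),
                    normalBeta = setNames(normalBeta, probeId),
                    tumourBeta = setNames(tumourBeta, probeId),
                    plantedChange = setNames(planted, probeId),
                    nClippedBetaShifts = nClipped))
}

#' Generate a TET2-like peak set and a bivalent gene list
#'
#' TET2-target promoters are drawn from 5hmC-marked promoters that carry
#' no planted methylation-gain probe (the planted exclusion structure
#' behind the overlap depletion analysis); each target receives one or two
#' peaks placed entirely within 1 kb of its TSS. The bivalent gene list is
#' assembled so that the configured fraction of gain-prone promoters and
#' the configured fraction of 5hmC-marked promoters are bivalent;
#' infeasible fractions raise an error.
#'
#' @param genes \code{GRanges} gene models.
#' @param truth truth list including per-probe planted changes.
#' @param config a \linkS4class{SimConfig}.
#' @param seed RNG seed.
#' @return list with \code{peaks} (\code{GRanges}), \code{bivalentGenes}
#'   (character) and \code{truth} (TET2 target and bivalent flags,
#'   gain-prone gene ids).
#' @export
simulatePeaksAndBivalents <- function(genes, truth, config,
                                      seed = config@seed) {
  set.seed(seed)
  gid <- genes$gene_id
  cls <- truth$promoterClass[gid]
  marked <- gid[cls != "unmarked"]
  plant <- truth$plantedChange
  probeGene <- truth$probeGene  # probe_id -> gene_id (true placement)
  gainProne <- unique(probeGene[names(plant)[plant == "gain"]])
  nTet2 <- round(config@tet2Fraction * length(marked))
  candidates <- setdiff(marked, gainProne)
  if (nTet2 > length(candidates))
    stop("tet2Fraction infeasible: only ", length(candidates),
         " gain-free marked promoters available")
  tet2 <- if (nTet2 > 0) sort(sample(candidates, nTet2)) else character(0)
  ## peaks within +/- 1 kb of each target TSS
  peakRows <- list()
  tssOf <- setNames(genes$tss, gid)
  chromOf <- setNames(as.character(seqnames(genes)), gid)
  for (g in tet2) {
    for (k in seq_len(sample(1:2, 1))) {
      w <- sample(200:500, 1)
      maxOff <- 1000L - w
      center0 <- sample(seq(-maxOff, maxOff), 1)  # start offset range
      s <- tssOf[g] + center0
      peakRows[[length(peakRows) + 1L]] <- data.frame(
        chrom = chromOf[g], start = max(1L, s),
        end = max(1L, s) + w - 1L, gene_id = g)
    }
  }
  peaks <- if (length(peakRows)) {
    pdf <- do.call(rbind, peakRows)
    GRanges(pdf$chrom, IRanges(pdf$start, pdf$end), gene_id = pdf$gene_id)
  } else GRanges()
  ## bivalent set: configured fraction of gain-prone promoters, topped up
  ## so the configured fraction of marked promoters is bivalent
  nBivGain <- round(config@bivalentGainFraction * length(gainProne))
  bivalent <- if (nBivGain > 0) sample(gainProne, nBivGain) else character(0)
  needMarked <- round(config@bivalentHmcFraction * length(marked))
  haveMarked <- length(intersect(bivalent, marked))
  if (haveMarked > needMarked)
    stop("bivalent fractions infeasible: gain-prone sampling already ",
         "exceeds the requested marked fraction")
  ## top up from marked promoters that are neither bivalent nor gain-prone
  ## so the realized gain fraction stays at its configured value
  pool <- setdiff(marked, union(bivalent, gainProne))
  extra <- needMarked - haveMarked
  if (extra > length(pool))
    stop("bivalentHmcFraction infeasible for the marked promoter count")
  if (extra > 0) bivalent <- c(bivalent, sample(pool, extra))
  bivalent <- sort(unique(bivalent))
  list(peaks = peaks, bivalentGenes = bivalent,
       truth = list(tet2Targets = tet2, gainProne = gainProne))
}

#' Simulate a complete synthetic cohort
#'
#' Runs the whole generator in a fixed order under seeds derived from
#' \code{config@seed}: genome and gene models, hmeDIP read sets
#' (\code{nDipNormal} normal IP, \code{nDipTumour} tumour IP, one input
#' per tissue), the Infinium-style manifest and intensity table for
#' \code{nPairs} matched pairs, and the TET2 peak / bivalent gene
#' structure. Identical configs give byte-identical cohorts.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param islands logical; disable to generate a genome without CpG-rich
#'   regimes.
#' @return an \linkS4class{HmcCohort}.
#' @examples
#' \donttest{
#' cohort <- simulateCohort(SimConfig(seed = 1, nGenes = 30L,
#'                                    chromLength = 500000L,
#'                                    nReadsIP = 5000L, nReadsInput = 5000L))
#' }
#' @export
simulateCohort <- function(config, islands = TRUE) {
  base <- config@seed
  gen <- simulateGenome(config, islands = islands, seed = base)
  readSets <- list()
  for (i in seq_len(config@nDipNormal)) {
    id <- sprintf("hmN%02d", i)
    readSets[[id]] <- simulateDipReads(gen$genes, gen$truth, "normal",
                                       config, id, seed = base + 1000L + i)
  }
  for (i in seq_len(config@nDipTumour)) {
    id <- sprintf("hmT%02d", i)
    readSets[[id]] <- simulateDipReads(gen$genes, gen$truth, "tumour",
                                       config, id, seed = base + 1100L + i)
  }
  readSets[["inputN"]] <- simulateDipReads(gen$genes, gen$truth, "input",
                                           config, "inputN",
                                           seed = base + 1200L)
  readSets[["inputT"]] <- simulateDipReads(gen$genes, gen$truth, "input",
                                           config, "inputT",
                                           seed = base + 1201L)
  inf <- simulateInfinium(gen$genes, gen$truth, config, seed = base + 2000L)
  truth <- c(gen$truth, inf$truth)
  truth$probeGene <- setNames(inf$probes$true_gene, inf$probes$probe_id)
  pk <- simulatePeaksAndBivalents(gen$genes, truth, config,
                                  seed = base + 3000L)
  truth <- c(truth, pk$truth)
  truth$bivalentFlag <- setNames(gen$genes$gene_id %in% pk$bivalentGenes,
                                 gen$genes$gene_id)
  truth$tet2Flag <- setNames(gen$genes$gene_id %in% pk$truth$tet2Targets,
                             gen$genes$gene_id)
  new("HmcCohort", genome = gen$genome, genes = gen$genes,
      probes = inf$probes, readSets = readSets,
      intensities = inf$intensities, pairing = inf$pairing,
      peaks = pk$peaks, bivalentGenes = pk$bivalentGenes, truth = truth,
      config = config)
}
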
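test_that("genome generation is deterministic and respects sizing limits", {
  cfg <- smallSimConfig()
  g1 <- simulateGenome(cfg)
  g2 <- simulateGenome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$promoterClass, g2$truth$promoterClass)
  ## genes do not overlap
  expect_equal(length(GenomicRanges::reduce(g1$genes)), length(g1$genes))
  ## TSS/TTS lie on interval boundaries, minus strand has tss > tts
  minus <- as.character(strand(g1$genes)) == "-"
  expect_true(all(g1$genes$tss[minus] > g1$genes$tts[minus]))
  expect_true(all(g1$genes$tss[!minus] < g1$genes$tts[!minus]))
  ## too many genes for the chromosome is a sizing error
  tiny <- SimConfig(seed = 1, nGenes = 100L, chromLength = 100000L)
  expect_error(simulateGenome(tiny), "too small")
})

test_that("island regimes drive the promoter CpG classes", {
  cfg <- smallSimConfig(seed = 13L)
  gen <- simulateGenome(cfg)
  ctx <- promoterContext(gen$genome, gen$genes)
  cls <- as.character(classifyPromoterCpG(ctx))
  truthCls <- gen$truth$promoterClass[gen$genes$gene_id]
  ## broad promoters carry the HCP regime, unmarked stay LCP
  expect_true(mean(cls[truthCls == "broad"] == "HCP") > 0.9)
  expect_true(mean(cls[truthCls == "unmarked"] == "LCP") > 0.9)
  ## with the island regime disabled every promoter is background (LCP)
  genOff <- simulateGenome(cfg, islands = FALSE)
  ctxOff <- promoterContext(genOff$genome, genOff$genes)
  expect_true(all(classifyPromoterCpG(ctxOff) == "LCP"))
})

test_that("read generation conserves counts and concentrates narrow promoters", {
  cfg <- smallSimConfig(seed = 17L)
  gen <- simulateGenome(cfg)
  rs <- simulateDipReads(gen$genes, gen$truth, "normal", cfg, "n1",
                         seed = 5)
  expect_equal(length(readIntervals(rs)), cfg@nReadsIP)
  expect_equal(totalMapped(rs), cfg@nReadsIP)
  ## determinism
  rs2 <- simulateDipReads(gen$genes, gen$truth, "normal", cfg, "n1",
                          seed = 5)
  expect_identical(start(readIntervals(rs)), start(readIntervals(rs2)))
  ## zero reads requested
  cfg0 <- smallSimConfig(); cfg0@nReadsInput <- 0L
  rs0 <- simulateDipReads(gen$genes, gen$truth, "input", cfg0, "i0")
  expect_length(readIntervals(rs0), 0)
  expect_equal(totalMapped(rs0), 0)
  ## narrow promoters: window fraction exceeds the gene-body fraction
  cls <- gen$truth$promoterClass[gen$genes$gene_id]
  narrowGenes <- gen$genes[cls == "narrow"]
  sc <- scorePromoters(rs, narrowGenes)
  expect_gt(sum(sc$narrow_count), sum(sc$body_count))
  ## and the planted TSS dip is present: no midpoints within 60 bp of TSS
  prom <- promoterWindow(narrowGenes, 1000, 500)
  mids <- start(readIntervals(rs)) + 25
  inProm <- countReadsInProbeWindows(rs, GRanges(
    seqnames(narrowGenes), IRanges(narrowGenes$tss, width = 1),
    probe_id = narrowGenes$gene_id), window = 100)
  expect_lt(sum(inProm$count), sum(sc$narrow_count) * 0.05)
})

test_that("input reads are indistinguishable from uniform background", {
  cfg <- smallSimConfig(seed = 19L)
  gen <- simulateGenome(cfg)
  rs <- simulateDipReads(gen$genes, gen$truth, "input", cfg, "in1",
                         seed = 7)
  ## rank-sum comparison of promoter-window vs matched-size random windows
  mids <- start(readIntervals(rs)) + 25
  promoterBins <- countReadsInProbeWindows(
    rs, GRanges(seqnames(gen$genes), IRanges(gen$genes$tss, width = 1),
                probe_id = gen$genes$gene_id), window = 1000)$count
  set.seed(1)
  rndPos <- sample(5000:(cfg@chromLength - 5000), length(gen$genes))
  randomBins <- countReadsInProbeWindows(
    rs, GRanges("chr1", IRanges(rndPos, width = 1),
                probe_id = as.character(seq_along(rndPos))),
    window = 1000)$count
  expect_gt(rankSumCompare(promoterBins, randomBins)$p, 0.01)
})

test_that("tumour scaling reproduces the configured net promoter RPM ratio", {
  cfg <- SimConfig(seed = 23, nGenes = 180L, chromLength = 2500000L,
                   nReadsIP = 40000L, nReadsInput = 40000L,
                   tumourScale = 0.3)
  gen <- simulateGenome(cfg)
  rsN <- simulateDipReads(gen$genes, gen$truth, "normal", cfg, "n",
                          seed = 31)
  rsT <- simulateDipReads(gen$genes, gen$truth, "tumour", cfg, "t",
                          seed = 32)
  rsI <- simulateDipReads(gen$genes, gen$truth, "input", cfg, "i",
                          seed = 33)
  ## input-subtracted promoter-window counts across > 100 marked promoters
  cls <- gen$truth$promoterClass[gen$genes$gene_id]
  marked <- gen$genes[cls != "unmarked"]
  expect_gte(length(marked), 100)
  winOf <- function(rs) sum(scorePromoters(rs, marked)$narrow_count +
                              scorePromoters(rs, marked)$body_count)
  netN <- winOf(rsN) - winOf(rsI)
  netT <- winOf(rsT) - winOf(rsI)
  ratio <- netT / netN
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.35)
})

test_that("Infinium synthesis recovers planted betas, effects and determinism", {
  cfg <- smallSimConfig(seed = 29L)
  gen <- simulateGenome(cfg)
  inf <- simulateInfinium(gen$genes, gen$truth, cfg, seed = 41)
  ## conservation: M + U equals the synthesised total (U = T - M)
  expect_true(all(inf$intensities$M + inf$intensities$U >= 100))
  expect_true(all(inf$intensities$M >= 0 & inf$intensities$U >= 0))
  ## byte-identical regeneration
  inf2 <- simulateInfinium(gen$genes, gen$truth, cfg, seed = 41)
  expect_identical(inf$intensities, inf2$intensities)
  ## noiseless, uncompressed synthesis recovers beta to 1/T quantisation
  cfgExact <- smallSimConfig(seed = 29L)
  cfgExact@betaNoiseSd <- 0
  cfgExact@typeIICompression <- 1
  infE <- simulateInfinium(gen$genes, gen$truth, cfgExact, seed = 41)
  bE <- betaValue(infE$intensities$M, infE$intensities$U)
  nid <- sprintf("N%02d", 1:cfgExact@nPairs)
  isN <- infE$intensities$sample_id %in% nid
  wantB <- infE$truth$normalBeta[infE$intensities$probe_id[isN]]
  expect_lt(max(abs(bE[isN] - wantB)), 1 / 100)
  ## planted gain probes show ~ +effect mean beta difference
  plant <- infE$truth$plantedChange
  gainProbes <- names(plant)[plant == "gain" &
                               infE$truth$normalBeta < 0.7]
  if (length(gainProbes)) {
    bAll <- betaValue(infE$intensities$M, infE$intensities$U)
    isT <- !isN
    dMean <- vapply(gainProbes, function(p) {
      sel <- infE$intensities$probe_id == p
      mean(bAll[sel & isT]) - mean(bAll[sel & isN])
    }, numeric(1))
    expect_lt(max(abs(dMean - cfgExact@effectSizeBeta)), 0.02)
  }
})

test_that("peaks sit within 1 kb of target TSSs and bivalent fractions are honoured", {
  co <- smallCohort()
  tr <- cohortTruth(co)
  g <- geneModels(co)
  ## construction invariant: every peak within +/- 1 kb of some TSS
  pk <- peakSet(co)
  tssW <- GRanges(seqnames(g), IRanges(g$tss - 1000, g$tss + 1000))
  within <- IRanges::overlapsAny(pk, tssW, type = "within")
  expect_true(all(within))
  ## realized bivalent-among-gain fraction within one promoter of target
  gainProne <- tr$gainProne
  biv <- bivalentGenes(co)
  want <- simConfig(co)@bivalentGainFraction * length(gainProne)
  expect_lte(abs(length(intersect(biv, gainProne)) - want), 1)
  ## realized bivalent-among-marked fraction
  cls <- tr$promoterClass
  marked <- names(cls)[cls != "unmarked"]
  wantM <- simConfig(co)@bivalentHmcFraction * length(marked)
  expect_lte(abs(length(intersect(biv, marked)) - wantM), 1)
  ## TET2 fraction 0 gives an empty peak set
  cfg0 <- smallSimConfig(); cfg0@tet2Fraction <- 0
  gen <- simulateGenome(cfg0)
  inf <- simulateInfinium(gen$genes, gen$truth, cfg0)
  truth <- c(gen$truth, inf$truth)
  truth$probeGene <- setNames(inf$probes$true_gene, inf$probes$probe_id)
  pk0 <- simulatePeaksAndBivalents(gen$genes, truth, cfg0)
  expect_length(pk0$peaks, 0)
})

test_that("whole-cohort generation is deterministic end to end", {
  cfg <- smallSimConfig(seed = 37L)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(as.character(genomeSeq(c1)), as.character(genomeSeq(c2)))
  expect_identical(intensityTable(c1), intensityTable(c2))
  expect_identical(start(peakSet(c1)), start(peakSet(c2)))
  expect_identical(bivalentGenes(c1), bivalentGenes(c2))
  expect_identical(cohortTruth(c1)$plantedChange,
                   cohortTruth(c2)$plantedChange)
})

test_that("cohort bundles round-trip through plain-text files", {
  co <- smallCohort()
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  back <- readCohort(dir)
  expect_identical(as.character(genomeSeq(back)), as.character(genomeSeq(co)))
  expect_equal(start(geneModels(back)), start(geneModels(co)))
  expect_equal(back@intensities$M, co@intensities$M)
  expect_equal(start(probeManifest(back)), start(probeManifest(co)))
  expect_equal(sort(names(readSets(back))), sort(names(readSets(co))))
  r1 <- readIntervals(readSets(back)[["hmN01"]])
  r2 <- readIntervals(readSets(co)[["hmN01"]])
  expect_equal(sort(start(r1)), sort(start(r2)))
  expect_equal(cohortTruth(back)$promoterClass, cohortTruth(co)$promoterClass)
  expect_equal(bivalentGenes(back), bivalentGenes(co))
  ## a missing file aborts naming the input stage
  file.remove(file.path(dir, "manifest.tsv"))
  expect_error(readCohort(dir), "stage 'input'")
})
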
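test_that("RPM normalisation has the unit definition and scale invariance", {
  rs <- makeReads(101, width = 30, totalMapped = 1e6, seqlen = 1000)
  cov <- normalizedCoverage(rs, c(chr1 = 1000L), binSize = 50L)
  v <- coverageValues(cov, "chr1")
  expect_equal(v[3], 1.0)          # read in bin [101,150] only
  expect_equal(sum(v), 1.0)
  ## duplicating every read and doubling the total leaves coverage unchanged
  rs2 <- makeReads(rep(101, 2), width = 30, totalMapped = 2e6)
  cov2 <- normalizedCoverage(rs2, c(chr1 = 1000L), binSize = 50L)
  expect_equal(coverageValues(cov2, "chr1"), v)
  expect_error(normalizedCoverage(makeReads(integer(0), totalMapped = 0),
                                  c(chr1 = 1000L)), "positive")
})

test_that("per-bin overlap counting matches a naive per-read loop", {
  set.seed(31)
  starts <- sample(1:4900, 400, replace = TRUE)
  rs <- makeReads(starts, width = 75, totalMapped = 400)
  cov <- normalizedCoverage(rs, c(chr1 = 5000L), binSize = 50L)
  ## oracle: loop over reads, incrementing every bin the read touches
  nb <- 100
  oracle <- numeric(nb)
  for (s in starts) {
    e <- s + 74
    bins <- ((s - 1) %/% 50 + 1):((e - 1) %/% 50 + 1)
    oracle[bins] <- oracle[bins] + 1
  }
  expect_equal(coverageValues(cov, "chr1"), oracle * 1e6 / 400)
})

test_that("input subtraction is elementwise, unclamped and grid-checked", {
  set.seed(32)
  rsA <- makeReads(sample(1:900, 50, TRUE), width = 40, totalMapped = 50)
  rsB <- makeReads(sample(1:900, 80, TRUE), width = 40, totalMapped = 80)
  a <- normalizedCoverage(rsA, c(chr1 = 1000L), 50L)
  b <- normalizedCoverage(rsB, c(chr1 = 1000L), 50L)
  net <- inputSubtract(a, b)
  expect_equal(coverageValues(net, "chr1"),
               coverageValues(a, "chr1") - coverageValues(b, "chr1"))
  expect_true(any(coverageValues(net, "chr1") < 0))
  ## ip == input gives the zero track; zero input is the identity
  expect_equal(coverageValues(inputSubtract(a, a), "chr1"),
               rep(0, 20))
  zero <- normalizedCoverage(makeReads(integer(0), totalMapped = 10),
                             c(chr1 = 1000L), 50L)
  expect_equal(coverageValues(inputSubtract(a, zero), "chr1"),
               coverageValues(a, "chr1"))
  bad <- normalizedCoverage(rsB, c(chr1 = 1000L), 25L)
  expect_error(inputSubtract(a, bad), "grid")
})

test_that("TSS metagene is oriented, localised and linear in genes", {
  seqlen <- c(chr1 = 20000L)
  ## plus-strand gene with one read just upstream of the TSS
  gP <- GRanges("chr1", IRanges(10001, 12000), strand = "+",
                gene_id = "gp", tss = 10001, tts = 12000)
  rs <- makeReads(9901, width = 50, totalMapped = 1e6)
  net <- normalizedCoverage(rs, seqlen, 50L)
  mp <- tssMetagene(net, gP, flank = 1000L)
  nz <- which(mp$mean > 0)
  expect_length(nz, 1)
  expect_lt(mp$position[nz], 0)
  ## the bin-grid-mirrored minus-strand configuration (TSS at a bin end,
  ## read the same two bins upstream) gives the identical oriented profile
  gM <- GRanges("chr1", IRanges(8051, 10050), strand = "-",
                gene_id = "gm", tss = 10050, tts = 8051)
  rsM <- makeReads(10101, width = 50, totalMapped = 1e6)
  mm <- tssMetagene(normalizedCoverage(rsM, seqlen, 50L), gM, flank = 1000L)
  expect_equal(mm$mean, mp$mean)
  ## two genes: profile is the mean of the individual profiles
  both <- c(gP, gM)
  rsBoth <- makeReads(c(9901, 10101), width = 50, totalMapped = 1e6)
  netBoth <- normalizedCoverage(rsBoth, seqlen, 50L)
  m2 <- tssMetagene(netBoth, both, flank = 1000L)
  m2a <- tssMetagene(netBoth, gP, flank = 1000L)
  m2b <- tssMetagene(netBoth, gM, flank = 1000L)
  expect_equal(m2$mean, (m2a$mean + m2b$mean) / 2)
  expect_equal(attr(m2, "n_genes"), 2)
})

test_that("metagene of uniform random reads is flat within Monte-Carlo error", {
  set.seed(33)
  L <- 200000L
  rs <- makeReads(sample(1:(L - 50), 40000, TRUE), width = 50,
                  totalMapped = 40000)
  g <- GRanges("chr1", IRanges(seq(20000, 180000, by = 20000), width = 5000),
               strand = "+", gene_id = letters[1:9])
  g$tss <- start(g); g$tts <- end(g)
  net <- normalizedCoverage(rs, c(chr1 = L), 50L)
  m <- tssMetagene(net, g, flank = 3000L)
  expect_lt(sd(m$mean) / mean(m$mean), 0.5)
  expect_gt(min(m$mean), 0)
})

test_that("feature distribution follows midpoint precedence and sums to one", {
  g <- GRanges("chr1", IRanges(10001, 15000), strand = "+",
               gene_id = "g", tss = 10001, tts = 15000)
  ## all reads inside the promoter window
  rs <- makeReads(rep(9500, 10), width = 50, totalMapped = 10)
  fd <- featureDistribution(rs, g)
  expect_equal(unname(fd), c(1, 0, 0))
  ## a midpoint at the promoter/gene-body boundary belongs to the promoter:
  ## promoter is [9001, 10500]; midpoint 10500 (start 10475, width 50)
  rsEdge <- makeReads(10475, width = 50, totalMapped = 1)
  expect_equal(unname(featureDistribution(rsEdge, g)), c(1, 0, 0))
  ## one bp further it is gene body
  rsIn <- makeReads(10476, width = 50, totalMapped = 1)
  expect_equal(unname(featureDistribution(rsIn, g)), c(0, 1, 0))
  expect_error(featureDistribution(makeReads(integer(0)), g), "empty")
})

test_that("random-read feature fractions equal a brute-force classification", {
  set.seed(34)
  L <- 100000L
  strands <- c("+", "-", "+")
  tss <- c(20000, 50000, 80000)
  g <- GRanges("chr1",
               IRanges(c(20000, 45001, 80000), c(24000, 50000, 86000)),
               strand = strands, gene_id = c("a", "b", "c"))
  g$tss <- ifelse(strands == "-", end(g), start(g))
  g$tts <- ifelse(strands == "-", start(g), end(g))
  starts <- sample(1:(L - 50), 3000, TRUE)
  rs <- makeReads(starts, width = 50, totalMapped = 3000)
  fd <- featureDistribution(rs, g)
  expect_equal(sum(fd), 1)
  ## oracle: classify each midpoint directly
  prom <- promoterWindow(g, 1000, 500)
  mids <- starts + 25
  inP <- vapply(mids, function(m)
    any(m >= start(prom) & m <= end(prom)), logical(1))
  inB <- vapply(mids, function(m)
    any(m >= start(g) & m <= end(g)), logical(1)) & !inP
  expect_equal(unname(fd),
               c(mean(inP), mean(inB), mean(!inP & !inB)))
})

test_that("probe-window counts respect the half-open boundary and an interval oracle", {
  probes <- GRanges("chr1", IRanges(5000, width = 1), probe_id = "p1")
  ## midpoint = start + 25 for width-50 reads
  atProbe <- makeReads(5000 - 25, width = 50, totalMapped = 1)
  expect_equal(countReadsInProbeWindows(atProbe, probes)$count, 1)
  ## midpoint exactly at pos + 100 is excluded (right edge open)
  atEdge <- makeReads(5100 - 25, width = 50, totalMapped = 1)
  expect_equal(countReadsInProbeWindows(atEdge, probes)$count, 0)
  justIn <- makeReads(5099 - 25, width = 50, totalMapped = 1)
  expect_equal(countReadsInProbeWindows(justIn, probes)$count, 1)
  leftIn <- makeReads(4900 - 25, width = 50, totalMapped = 1)
  expect_equal(countReadsInProbeWindows(leftIn, probes)$count, 1)
  leftOut <- makeReads(4899 - 25, width = 50, totalMapped = 1)
  expect_equal(countReadsInProbeWindows(leftOut, probes)$count, 0)
  expect_error(countReadsInProbeWindows(atProbe, probes, window = 201),
               "even")
})

test_that("multi-sample probe counts match the brute-force oracle with RPM averaging", {
  set.seed(35)
  pos <- sample(2000:98000, 40)
  probes <- GRanges("chr1", IRanges(pos, width = 1),
                    probe_id = sprintf("p%02d", seq_along(pos)))
  s1 <- sample(1:99000, 2000, TRUE)
  s2 <- sample(1:99000, 3000, TRUE)
  rs1 <- makeReads(s1, width = 50, totalMapped = 4000)
  rs2 <- makeReads(s2, width = 50, totalMapped = 6000)
  got <- countReadsInProbeWindows(list(rs1, rs2), probes, window = 200)
  mids1 <- s1 + 25; mids2 <- s2 + 25
  o1 <- vapply(pos, function(p) sum(mids1 >= p - 100 & mids1 <= p + 99),
               numeric(1))
  o2 <- vapply(pos, function(p) sum(mids2 >= p - 100 & mids2 <= p + 99),
               numeric(1))
  expect_equal(got$count, o1 + o2)
  expect_equal(got$rpm_mean, (o1 * 1e6 / 4000 + o2 * 1e6 / 6000) / 2)
})
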
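## Shared fixtures built in code. Heavy objects are memoised per test run.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

.fixtures <- new.env(parent = emptyenv())

## A small cohort for fast structural tests.
smallSimConfig <- function(seed = 11L) {
  SimConfig(seed = seed, nGenes = 40L, chromLength = 700000L,
            nReadsIP = 12000L, nReadsInput = 12000L,
            nDipNormal = 2L, nDipTumour = 2L, nPairs = 6L)
}

smallCohort <- function() {
  if (is.null(.fixtures$small))
    .fixtures$small <- simulateCohort(smallSimConfig())
  .fixtures$small
}

## Random DNA string with a given GC level.
randomSeq <- function(n, gc = 0.4) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## Brute-force window CpG statistics straight from the definition:
## character-level loop, independent of the package's vectorised path.
oracleWindowStats <- function(seqChar, width, step = 1L) {
  x <- strsplit(seqChar, "")[[1]]
  L <- length(x)
  starts <- seq(1L, L - width + 1L, by = step)
  t(vapply(starts, function(s) {
    w <- x[s:(s + width - 1L)]
    nC <- sum(w == "C"); nG <- sum(w == "G")
    nCpG <- sum(w[-length(w)] == "C" & w[-1] == "G")
    oe <- if (nC > 0 && nG > 0) nCpG * width / (nC * nG) else 0
    c(start = s, gc = (nC + nG) / width, obsExp = oe)
  }, c(start = 0, gc = 0, obsExp = 0)))
}

## Oracle promoter class from exhaustive windows at the same offsets.
oraclePromoterClass <- function(seqChar, width = 500L, step = 5L) {
  st <- oracleWindowStats(seqChar, width, step)
  if (any(st[, "gc"] >= 0.55 & st[, "obsExp"] >= 0.75)) "HCP"
  else if (all(st[, "obsExp"] < 0.48)) "LCP"
  else "ICP"
}

## Oracle island calls: union of qualifying 200 bp windows, merged.
oracleIslands <- function(seqChar, width = 200L) {
  st <- oracleWindowStats(seqChar, width, 1L)
  ok <- st[, "gc"] >= 0.50 & st[, "obsExp"] >= 0.60
  if (!any(ok)) return(matrix(numeric(0), ncol = 2))
  covered <- rep(FALSE, nchar(seqChar))
  for (s in st[ok, "start"]) covered[s:(s + width - 1L)] <- TRUE
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

## Simple read set on one chromosome from explicit start positions.
makeReads <- function(starts, width = 50L, chrom = "chr1",
                      totalMapped = length(starts), sampleId = "s",
                      seqlen = NULL) {
  gr <- GRanges(rep(chrom, length(starts)), IRanges(starts, width = width))
  if (!is.null(seqlen))
    GenomeInfoDb::seqlengths(gr) <- setNames(seqlen, chrom)
  AlignedReadSet(sampleId, gr, totalMapped = totalMapped)
}
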
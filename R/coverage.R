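## Bin index (1-based) of a 1-based genomic position on a fixed grid.
.binIndex <- function(pos, binSize) (pos - 1L) %/% binSize + 1L

## 1-based midpoint of read intervals: start + floor(width/2).
.readMidpoints <- function(reads) {
  GRanges(seqnames(reads),
          IRanges(start(reads) + width(reads) %/% 2L, width = 1L))
}

#' Per-million-normalised binned read coverage
#'
#' Bins the genome at \code{binSize} and counts, per bin, the reads whose
#' interval overlaps the bin (a read spanning k bins contributes to each of
#' the k), scaled to reads per million mapped reads
#' (\code{count * 1e6 / totalMapped}).
#'
#' @param readSet an \linkS4class{AlignedReadSet}; \code{totalMapped} must
#'   be positive.
#' @param seqlens named integer chromosome lengths.
#' @param binSize bin width in bp.
#' @return A \linkS4class{BinnedCoverage}.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10, width = 30))
#' rs <- AlignedReadSet("s", gr, totalMapped = 1e6)
#' coverageValues(normalizedCoverage(rs, c(chr1 = 1000L)), "chr1")[1]
#' @export
normalizedCoverage <- function(readSet, seqlens, binSize = 50L) {
  if (totalMapped(readSet) <= 0)
    stop("totalMapped must be positive for RPM normalisation")
  binSize <- as.integer(binSize)
  reads <- readIntervals(readSet)
  vals <- lapply(names(seqlens), function(chr) {
    nb <- as.integer(ceiling(seqlens[[chr]] / binSize))
    tiles <- GRanges(chr, IRanges(start = (seq_len(nb) - 1L) * binSize + 1L,
                                  end = pmin(seq_len(nb) * binSize,
                                             seqlens[[chr]])))
    cnt <- countOverlaps(tiles, reads[as.character(seqnames(reads)) == chr])
    cnt * 1e6 / totalMapped(readSet)
  })
  names(vals) <- names(seqlens)
  new("BinnedCoverage", binSize = binSize, values = vals,
      seqlengths = setNames(as.integer(seqlens), names(seqlens)),
      subtracted = FALSE)
}

#' Subtract an input track from an IP track
#'
#' Elementwise \code{ip - input} on matching bin grids. Negative net values
#' are retained, not clamped.
#'
#' @param ip,input \linkS4class{BinnedCoverage} objects on identical grids.
#' @return A \linkS4class{BinnedCoverage} flagged as subtracted.
#' @export
inputSubtract <- function(ip, input) {
  if (ip@binSize != input@binSize ||
      !identical(ip@seqlengths, input@seqlengths))
    stop("ip and input coverage are on different bin grids")
  vals <- Map(`-`, ip@values, input@values)
  new("BinnedCoverage", binSize = ip@binSize, values = vals,
      seqlengths = ip@seqlengths, subtracted = TRUE)
}

#' Mean coverage profile around TSSs (metagene)
#'
#' For each gene, extracts net coverage over \code{[TSS - flank, TSS +
#' flank)}, orients it 5' to 3' (reversed for minus-strand genes), and
#' averages across genes. Genes whose window would run off a chromosome end
#' are excluded.
#'
#' @param net a \linkS4class{BinnedCoverage} (typically input-subtracted).
#' @param genes \code{GRanges} gene models.
#' @param flank half-width in bp; must be a multiple of the bin size.
#' @return data.frame with \code{position} (bp offset of each bin centre
#'   from the TSS bin) and \code{mean} coverage; attribute \code{n_genes}.
#' @export
tssMetagene <- function(net, genes, flank = 3000L) {
  bs <- net@binSize
  if (flank %% bs != 0) stop("flank must be a multiple of the bin size")
  nb <- as.integer(flank / bs)
  chrAll <- as.character(seqnames(genes))
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  profs <- list()
  for (i in seq_along(genes)) {
    v <- net@values[[chrAll[i]]]
    if (is.null(v)) next
    b0 <- .binIndex(tss[i], bs)
    ## oriented so the TSS bin sits at position nb + 1 on both strands
    idx <- if (minus[i]) (b0 + nb):(b0 - nb + 1L) else
      (b0 - nb):(b0 + nb - 1L)
    if (min(idx) < 1L || max(idx) > length(v)) next
    profs[[length(profs) + 1L]] <- v[idx]
  }
  if (!length(profs)) stop("no gene has a complete metagene window")
  m <- colMeans(do.call(rbind, profs))
  out <- data.frame(position = seq(-nb, nb - 1L) * bs + bs / 2, mean = m)
  attr(out, "n_genes") <- length(profs)
  out
}

#' Distribution of reads over promoter, gene body and intergenic space
#'
#' Assigns each read by its midpoint with precedence promoter > gene body >
#' intergenic, where promoters are the -1 kb/+0.5 kb TSS windows and gene
#' bodies the TSS..TTS intervals. Fractions sum to 1 exactly.
#'
#' @param readSet an \linkS4class{AlignedReadSet}; must be non-empty.
#' @param genes \code{GRanges} gene models.
#' @param upstream,downstream promoter window extent in bp.
#' @return named numeric vector \code{c(promoter=, gene_body=, intergenic=)}.
#' @export
featureDistribution <- function(readSet, genes, upstream = 1000L,
                                downstream = 500L) {
  reads <- readIntervals(readSet)
  if (!length(reads)) stop("empty read set")
  mids <- .readMidpoints(reads)
  prom <- promoterWindow(genes, upstream, downstream)
  inProm <- overlapsAny(mids, prom, ignore.strand = TRUE)
  inBody <- overlapsAny(mids, genes, ignore.strand = TRUE) & !inProm
  n <- length(mids)
  c(promoter = sum(inProm) / n, gene_body = sum(inBody) / n,
    intergenic = (n - sum(inProm) - sum(inBody)) / n)
}

#' Count hmeDIP reads in fixed windows around array probes
#'
#' Counts reads whose midpoint falls in the half-open window
#' \code{[pos - window/2, pos + window/2)} centred on each probe. With
#' several samples, raw counts are summed and per-sample RPM-scaled counts
#' averaged (\code{rpm_mean}), the score used to rank 5hmC-high/low loci.
#'
#' @param readSets an \linkS4class{AlignedReadSet} or list of them.
#' @param probes \code{GRanges} width-1 probe positions with
#'   \code{probe_id}.
#' @param window even window width in bp.
#' @return data.frame \code{probe_id}, \code{count} (raw sum),
#'   \code{rpm_mean}.
#' @export
countReadsInProbeWindows <- function(readSets, probes, window = 200L) {
  if (window %% 2L != 0L) stop("window must be even")
  if (is(readSets, "AlignedReadSet")) readSets <- list(readSets)
  half <- window %/% 2L
  win <- GRanges(seqnames(probes),
                 IRanges(start(probes) - half, start(probes) + half - 1L))
  raw <- matrix(0, nrow = length(probes), ncol = length(readSets))
  rpm <- raw
  for (j in seq_along(readSets)) {
    rs <- readSets[[j]]
    cnt <- countOverlaps(win, .readMidpoints(readIntervals(rs)),
                         ignore.strand = TRUE)
    raw[, j] <- cnt
    rpm[, j] <- cnt * 1e6 / totalMapped(rs)
  }
  data.frame(probe_id = probes$probe_id, count = rowSums(raw),
             rpm_mean = rowMeans(rpm))
}
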
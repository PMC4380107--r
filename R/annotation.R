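#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   promoters trim mcols mcols<- countOverlaps findOverlaps
#'   reduce resize shift strand<-
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits Rle
#' @importFrom Biostrings DNAStringSet letterFrequency
#'   letterFrequencyInSlidingView vcountPattern readDNAStringSet
#'   writeXStringSet reverseComplement subseq
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels
NULL

## Windowed GC / CpG observed-expected statistics over every start of a
## fixed-width window. Returns a data.frame with one row per window start.
## obs/exp = (#CpG * L) / (#C * #G); defined as 0 when #C or #G is 0.
.windowCpGStats <- function(seq, width) {
  seq <- DNAStringSet(seq)[[1]]
  L <- length(seq)
  if (L < width) return(NULL)
  cg <- letterFrequencyInSlidingView(seq, width, c("C", "G"))
  ## CpG dinucleotide count per window: a CpG starting at i belongs to the
  ## window [s, s+width) iff s <= i <= s+width-2 (both bases inside).
  isC <- letterFrequencyInSlidingView(seq, 1L, "C")[, 1] == 1
  isG <- letterFrequencyInSlidingView(seq, 1L, "G")[, 1] == 1
  cpg <- as.integer(isC[-L] & isG[-1])
  cum <- c(0L, cumsum(cpg))
  nStarts <- L - width + 1L
  starts <- seq_len(nStarts)
  nCpG <- cum[starts + width - 1L] - cum[starts]
  nC <- cg[, "C"]
  nG <- cg[, "G"]
  oe <- ifelse(nC > 0 & nG > 0, nCpG * width / (nC * nG), 0)
  data.frame(start = seq_len(nStarts), gc = (nC + nG) / width, obsExp = oe,
             nCpG = nCpG, nC = nC, nG = nG)
}

#' Detect CpG islands in a DNA sequence
#'
#' Scans a sequence with a 200 bp window at 1 bp step and reports the union
#' of all windows meeting the Gardiner-Garden criteria (GC fraction >= 0.50
#' and CpG observed/expected >= 0.60), merged into maximal regions. The
#' observed/expected ratio is \code{(#CpG * L) / (#C * #G)} and is defined
#' as 0 when a window contains no C or no G. Reported regions carry the GC
#' fraction and obs/exp ratio recomputed over the merged region.
#'
#' @param seq a \code{DNAString}, \code{DNAStringSet} of length 1, or
#'   character scalar over A/C/G/T/N (N never matches C or G).
#' @param chrom chromosome name used in the returned \code{GRanges}.
#' @param windowWidth scan window width in bp.
#' @param minGC,minObsExp window inclusion thresholds.
#' @return \code{GRanges} of islands with metadata columns
#'   \code{gc_fraction} and \code{obs_exp_cpg}; empty when the sequence is
#'   shorter than the window.
#' @examples
#' findCpGIslands(paste(rep("CG", 250), collapse = ""))
#' @export
findCpGIslands <- function(seq, chrom = "chr1", windowWidth = 200L,
                           minGC = 0.50, minObsExp = 0.60) {
  stats <- .windowCpGStats(seq, windowWidth)
  empty <- GRanges(seqnames = character(), IRanges(),
                   gc_fraction = numeric(), obs_exp_cpg = numeric())
  if (is.null(stats)) return(empty)
  ok <- stats$gc >= minGC & stats$obsExp >= minObsExp
  if (!any(ok)) return(empty)
  win <- IRanges(stats$start[ok], width = windowWidth)
  merged <- IRanges::reduce(win)
  s <- DNAStringSet(seq)[[1]]
  gc <- numeric(length(merged)); oe <- numeric(length(merged))
  for (i in seq_along(merged)) {
    sub <- subseq(s, IRanges::start(merged)[i], IRanges::end(merged)[i])
    L <- length(sub)
    f <- letterFrequency(sub, c("C", "G"))
    nCpG <- vcountPattern("CG", DNAStringSet(sub))
    gc[i] <- sum(f) / L
    oe[i] <- if (f[["C"]] > 0 && f[["G"]] > 0) nCpG * L / (f[["C"]] * f[["G"]]) else 0
  }
  GRanges(chrom, merged, gc_fraction = gc, obs_exp_cpg = oe)
}

#' Classify promoter CpG content as HCP / ICP / LCP
#'
#' Applies the three-class windowed rule to promoter sequence context:
#' a promoter is \code{HCP} if any 500 bp window has GC fraction >= 0.55
#' and CpG observed/expected >= 0.75, \code{LCP} if no 500 bp window
#' reaches observed/expected 0.48, and \code{ICP} otherwise. Windows slide
#' at a 5 bp offset across the supplied context (TSS -1300 to +500 bp when
#' extracted with \code{\link{promoterContext}}).
#'
#' @param seqs \code{DNAStringSet} (or character vector) of promoter
#'   context sequences, each at least 500 bp.
#' @param windowWidth,step window geometry in bp.
#' @param hcpGC,hcpObsExp,lcpObsExp class thresholds.
#' @return factor with levels \code{HCP}, \code{ICP}, \code{LCP}.
#' @examples
#' classifyPromoterCpG(c(strrep("AT", 400), strrep("CG", 400)))
#' @export
classifyPromoterCpG <- function(seqs, windowWidth = 500L, step = 5L,
                                hcpGC = 0.55, hcpObsExp = 0.75,
                                lcpObsExp = 0.48) {
  seqs <- DNAStringSet(seqs)
  if (any(Biostrings::width(seqs) < windowWidth))
    stop("all promoter sequences must be at least ", windowWidth, " bp")
  cls <- vapply(seq_along(seqs), function(i) {
    st <- .windowCpGStats(seqs[[i]], windowWidth)
    keep <- seq(1L, nrow(st), by = step)
    st <- st[keep, , drop = FALSE]
    if (any(st$gc >= hcpGC & st$obsExp >= hcpObsExp)) "HCP"
    else if (all(st$obsExp < lcpObsExp)) "LCP"
    else "ICP"
  }, character(1))
  factor(cls, levels = c("HCP", "ICP", "LCP"))
}

#' Strand-aware promoter windows around gene TSSs
#'
#' Returns the promoter window \code{[TSS - upstream, TSS + downstream)}
#' for plus-strand genes and its mirror image for minus-strand genes,
#' trimmed to chromosome bounds. This is the -1 kb/+0.5 kb window used for
#' narrow-profile read counting when called with the defaults.
#'
#' @param genes \code{GRanges} gene models (strand set; the TSS is the
#'   strand-aware 5' end); \code{seqlengths} are used for trimming when
#'   available.
#' @param upstream,downstream window extent in bp; both zero is an error
#'   (empty window).
#' @return \code{GRanges} of promoter windows, parallel to \code{genes}.
#' @examples
#' g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10001, 12000),
#'                             strand = "+")
#' promoterWindow(g)
#' @export
promoterWindow <- function(genes, upstream = 1000L, downstream = 500L) {
  if (upstream < 0 || downstream < 0)
    stop("upstream and downstream must be >= 0")
  if (upstream + downstream == 0)
    stop("empty promoter window: upstream and downstream are both 0")
  w <- suppressWarnings(promoters(genes, upstream = upstream,
                                  downstream = downstream))
  suppressWarnings(trim(w))
}

#' Extract promoter sequence context around each TSS
#'
#' Pulls the strand-oriented sequence from \code{upstream} bp before to
#' \code{downstream} bp after the TSS (reverse-complemented for minus-strand
#' genes) for CpG-content classification.
#'
#' @param genome \code{DNAStringSet} named by chromosome.
#' @param genes \code{GRanges} gene models.
#' @param upstream,downstream context extent in bp (defaults -1300/+500).
#' @return \code{DNAStringSet} named by \code{gene_id} (or index).
#' @export
promoterContext <- function(genome, genes, upstream = 1300L,
                            downstream = 500L) {
  win <- promoterWindow(genes, upstream, downstream)
  seqs <- DNAStringSet(vapply(seq_along(win), function(i) {
    chr <- as.character(seqnames(win))[i]
    s <- max(1L, start(win)[i])
    e <- min(length(genome[[chr]]), end(win)[i])
    as.character(subseq(genome[[chr]], s, e))
  }, character(1)))
  minus <- as.character(strand(win)) == "-"
  seqs[minus] <- reverseComplement(seqs[minus])
  names(seqs) <- if (!is.null(genes$gene_id)) genes$gene_id else
    as.character(seq_along(win))
  seqs
}

#' Assign array probes to the nearest promoter
#'
#' Each probe is assigned to the gene whose TSS is closest by absolute
#' strand-aware signed distance (negative = upstream of the TSS), provided
#' that distance does not exceed \code{maxDistance} (inclusive of the
#' default 1,499 bp, exclusive of 1,500). Ties are broken by lexicographic
#' gene id.
#'
#' @param probes \code{GRanges} of width-1 probe positions with a
#'   \code{probe_id} column.
#' @param genes \code{GRanges} gene models with \code{gene_id}.
#' @param maxDistance maximal absolute probe-TSS distance (bp, inclusive).
#' @return \code{probes} with metadata columns \code{gene_id} (NA when
#'   unassigned) and \code{distance_to_tss}.
#' @export
assignProbesToPromoters <- function(probes, genes, maxDistance = 1499L) {
  tssPos <- ifelse(as.character(strand(genes)) == "-", end(genes),
                   start(genes))
  geneChr <- as.character(seqnames(genes))
  geneMinus <- as.character(strand(genes)) == "-"
  gid <- genes$gene_id
  probeChr <- as.character(seqnames(probes))
  pos <- start(probes)
  assigned <- rep(NA_character_, length(probes))
  dist <- rep(NA_integer_, length(probes))
  for (chr in unique(probeChr)) {
    gi <- which(geneChr == chr)
    if (!length(gi)) next
    pi <- which(probeChr == chr)
    ## all-pairs distances per chromosome; cohort sizes keep this small
    dmat <- outer(pos[pi], tssPos[gi], "-")          # probe - tss
    dmat[, geneMinus[gi]] <- -dmat[, geneMinus[gi], drop = FALSE]
    for (k in seq_along(pi)) {
      dd <- dmat[k, ]
      ok <- which(abs(dd) <= maxDistance)
      if (!length(ok)) next
      best <- ok[order(abs(dd[ok]), gid[gi][ok])][1]
      assigned[pi[k]] <- gid[gi][best]
      dist[pi[k]] <- dd[best]
    }
  }
  mcols(probes)$gene_id <- assigned
  mcols(probes)$distance_to_tss <- dist
  probes
}
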
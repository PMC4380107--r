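#' Select 5hmC-high and 5hmC-low locus sets by ranking
#'
#' Ranks array loci by their 5hmC probe-window score: the top \code{topN}
#' by descending score form the 5hmC-high set and the \code{topN} by
#' ascending score (zeros, i.e. undetected, first) the 5hmC-low set. Ties
#' are broken by probe id. The two sets are disjoint by construction; it
#' is an error to request more than half the loci.
#'
#' @param probeCounts data.frame with \code{probe_id} and a score column
#'   (\code{rpm_mean} preferred, else \code{count}).
#' @param topN set size.
#' @return list with character vectors \code{high} and \code{low}.
#' @export
selectHighLowLoci <- function(probeCounts, topN) {
  score <- if ("rpm_mean" %in% names(probeCounts)) probeCounts$rpm_mean
  else probeCounts$count
  id <- as.character(probeCounts$probe_id)
  if (2 * topN > length(id))
    stop("2 * topN exceeds the number of loci")
  high <- id[order(-score, id)][seq_len(topN)]
  low <- id[order(score, id)][seq_len(topN)]
  list(high = high, low = low)
}

#' Cross-tabulate methylation change within a locus set
#'
#' Restricts differential methylation calls to a locus set and reports how
#' many probes changed significantly and the gain/loss split among them.
#' Proportions are \code{NA} when no probe in the set is significant.
#'
#' @param lociIds character vector of probe ids (non-empty).
#' @param diffmeth output of \code{\link{weightedDiffMeth}}.
#' @return list with \code{n_selected}, \code{n_significant},
#'   \code{n_gain}, \code{n_loss}, \code{prop_gain}, \code{prop_loss}.
#' @export
crosstabMethylation <- function(lociIds, diffmeth) {
  if (!length(lociIds)) stop("empty locus set")
  sub <- diffmeth[diffmeth$probe_id %in% lociIds, , drop = FALSE]
  nG <- sum(sub$label == "gain"); nL <- sum(sub$label == "loss")
  nS <- nG + nL
  list(n_selected = length(lociIds), n_significant = nS, n_gain = nG,
       n_loss = nL,
       prop_gain = if (nS > 0) nG / nS else NA_real_,
       prop_loss = if (nS > 0) nL / nS else NA_real_)
}

#' Promoters targeted by ChIP peaks near the TSS
#'
#' A promoter is a target when its TSS +/- \code{flank} window overlaps at
#' least one peak by at least 1 bp.
#'
#' @param peaks \code{GRanges} peak intervals.
#' @param genes \code{GRanges} gene models with \code{gene_id}.
#' @param flank TSS flank in bp (default 1 kb).
#' @return character vector of target gene ids.
#' @export
tet2TargetPromoters <- function(peaks, genes, flank = 1000L) {
  win <- promoterWindow(genes, upstream = flank, downstream = flank)
  hit <- overlapsAny(win, peaks, ignore.strand = TRUE)
  genes$gene_id[hit]
}

#' Overlap depletion / enrichment test between two sets
#'
#' Under the binomial null each of the \code{|A|} members of set A falls in
#' set B independently with probability \code{q = |B| / n}; the one-sided
#' depletion p-value is \code{P(Bin(|A|, q) <= k)} for the observed
#' overlap \code{k}, and the enrichment side is also reported. A
#' hypergeometric (sampling without replacement) variant is available.
#'
#' @param setA,setB vectors of ids, both subsets of \code{universe}.
#' @param universe non-empty vector of ids.
#' @param null \code{"binomial"} (default) or \code{"hypergeometric"}.
#' @return list with \code{nA}, \code{nB}, \code{overlap}, \code{n},
#'   \code{expected}, \code{p_depletion}, \code{p_enrichment}.
#' @export
overlapDepletionTest <- function(setA, setB, universe,
                                 null = c("binomial", "hypergeometric")) {
  null <- match.arg(null)
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  setA <- unique(setA); setB <- unique(setB)
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("setA and setB must be subsets of the universe")
  n <- length(universe); nA <- length(setA); nB <- length(setB)
  k <- length(intersect(setA, setB))
  if (null == "binomial") {
    q <- nB / n
    pDep <- pbinom(k, nA, q)
    pEnr <- pbinom(k - 1, nA, q, lower.tail = FALSE)
  } else {
    pDep <- phyper(k, nB, n - nB, nA)
    pEnr <- phyper(k - 1, nB, n - nB, nA, lower.tail = FALSE)
  }
  list(nA = nA, nB = nB, overlap = k, n = n, expected = nA * nB / n,
       p_depletion = pDep, p_enrichment = pEnr)
}

#' Three-way Venn decomposition of promoter sets
#'
#' Counts the seven regions of three sets (5hmC-marked, bivalent,
#' methylation-gain promoters) plus the outside remainder over a shared
#' universe, and reports the headline fractions: the bivalent share of
#' gain promoters and the bivalent share of 5hmC promoters.
#'
#' @param hmc,bivalent,gain vectors of gene ids.
#' @param universe vector of all gene ids (regions are counted within it).
#' @return list with \code{counts} (named integer vector of the 8
#'   regions), \code{frac_gain_bivalent}, \code{frac_hmc_bivalent}.
#' @export
vennThreeWay <- function(hmc, bivalent, gain, universe) {
  universe <- unique(universe)
  a <- universe %in% hmc; b <- universe %in% bivalent
  c_ <- universe %in% gain
  counts <- c(
    hmc_only = sum(a & !b & !c_),
    bivalent_only = sum(!a & b & !c_),
    gain_only = sum(!a & !b & c_),
    hmc_bivalent = sum(a & b & !c_),
    hmc_gain = sum(a & !b & c_),
    bivalent_gain = sum(!a & b & c_),
    all_three = sum(a & b & c_),
    outside = sum(!a & !b & !c_))
  nGain <- sum(c_); nHmc <- sum(a)
  list(counts = counts,
       frac_gain_bivalent = if (nGain > 0) sum(b & c_) / nGain else NA_real_,
       frac_hmc_bivalent = if (nHmc > 0) sum(a & b) / nHmc else NA_real_)
}

#' Fraction of bisulfite-resistant signal attributable to 5hmC
#'
#' Bisulfite conversion does not distinguish 5mC from 5hmC, so the
#' methylation reported by an Infinium array conflates the two. Given
#' global percentages of hydroxymethylated and methylated cytosines (e.g.
#' from mass spectrometry), the share of the combined signal due to 5hmC
#' is \code{pctHmc / (pctHmc + pctMc)}.
#'
#' @param pctHmc,pctMc non-negative global percentages; not both zero.
#' @return the fraction in [0, 1].
#' @examples
#' hmcFractionOfBisulfiteSignal(0.118, 4.8)
#' @export
hmcFractionOfBisulfiteSignal <- function(pctHmc, pctMc) {
  if (any(pctHmc < 0) || any(pctMc < 0))
    stop("percentages must be non-negative")
  if (any(pctHmc + pctMc == 0)) stop("pctHmc and pctMc are both zero")
  pctHmc / (pctHmc + pctMc)
}

#' Methylation change at promoters retaining 5hmC in tumours
#'
#' Promoters whose tumour probe-window 5hmC score reaches
#' \code{detectFloor} form the persistent set; the gain and loss fractions
#' are computed over that set (the set size is the denominator). An empty
#' persistent set is reported, not an error.
#'
#' @param tumourScores data.frame with \code{gene_id} and \code{rpm_mean}
#'   (tumour-sample probe-window scores aggregated per promoter).
#' @param promoterLabels named character vector (gene id ->
#'   gain/loss/none).
#' @param detectFloor minimal score counted as detected.
#' @return list with \code{n_persistent}, \code{n_gain}, \code{n_loss},
#'   \code{frac_gain}, \code{frac_loss}, \code{persistent} (gene ids).
#' @export
persistentHmcCrosstab <- function(tumourScores, promoterLabels,
                                  detectFloor = 1) {
  keep <- tumourScores$gene_id[tumourScores$rpm_mean >= detectFloor]
  lab <- promoterLabels[keep]
  nG <- sum(lab == "gain", na.rm = TRUE)
  nL <- sum(lab == "loss", na.rm = TRUE)
  n <- length(keep)
  list(n_persistent = n, n_gain = nG, n_loss = nL,
       frac_gain = if (n > 0) nG / n else NA_real_,
       frac_loss = if (n > 0) nL / n else NA_real_,
       persistent = keep)
}

#' Aggregate probe-level gain/loss calls to promoters
#'
#' A promoter is labelled by its significant probes: any significant probe
#' confers its label, and if a promoter carries both gain- and
#' loss-labelled probes the most significant (smallest p) wins.
#'
#' @param diffmeth output of \code{\link{weightedDiffMeth}}.
#' @param probeGene named character vector probe_id -> gene_id (NA for
#'   unassigned probes).
#' @return named character vector gene_id -> gain/loss/none.
#' @export
promoterMethylationState <- function(diffmeth, probeGene) {
  g <- probeGene[as.character(diffmeth$probe_id)]
  keep <- !is.na(g)
  dm <- diffmeth[keep, , drop = FALSE]
  g <- g[keep]
  out <- setNames(rep("none", length(unique(g))), unique(g))
  sig <- dm$label != "none"
  if (any(sig)) {
    dms <- dm[sig, , drop = FALSE]
    gs <- g[sig]
    ord <- order(dms$p)
    for (i in rev(ord)) out[gs[i]] <- dms$label[i]
  }
  out
}
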
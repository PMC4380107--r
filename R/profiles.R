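#' Score promoters by narrow-window and gene-body 5hmC read content
#'
#' Counts read midpoints inside the -1 kb/+0.5 kb promoter window and
#' inside the gene body (TSS..TTS) per gene, and ranks genes by descending
#' count (rank 1 = highest) with ties broken by ascending gene id. With
#' several samples the ranking score is the mean of per-sample RPM-scaled
#' counts; raw counts are the per-sample sums.
#'
#' @param readSets an \linkS4class{AlignedReadSet} or list of them
#'   (normal-tissue IP samples for the reference ranking).
#' @param genes \code{GRanges} gene models with \code{gene_id}; TSS must
#'   differ from TTS.
#' @param upstream,downstream promoter window extent in bp.
#' @return data.frame with \code{gene_id}, \code{narrow_count},
#'   \code{body_count}, \code{narrow_rpm}, \code{body_rpm},
#'   \code{narrow_rank}, \code{body_rank}.
#' @export
scorePromoters <- function(readSets, genes, upstream = 1000L,
                           downstream = 500L) {
  if (is(readSets, "AlignedReadSet")) readSets <- list(readSets)
  stopifnot(all(width(genes) > 1L))
  prom <- promoterWindow(genes, upstream, downstream)
  nRaw <- bRaw <- nRpm <- bRpm <- numeric(length(genes))
  for (rs in readSets) {
    mids <- .readMidpoints(readIntervals(rs))
    cn <- countOverlaps(prom, mids, ignore.strand = TRUE)
    cb <- countOverlaps(genes, mids, ignore.strand = TRUE)
    nRaw <- nRaw + cn; bRaw <- bRaw + cb
    nRpm <- nRpm + cn * 1e6 / totalMapped(rs)
    bRpm <- bRpm + cb * 1e6 / totalMapped(rs)
  }
  k <- length(readSets)
  gid <- genes$gene_id
  nRank <- integer(length(gid)); bRank <- integer(length(gid))
  nRank[order(-nRpm, gid)] <- seq_along(gid)
  bRank[order(-bRpm, gid)] <- seq_along(gid)
  data.frame(gene_id = gid, narrow_count = nRaw, body_count = bRaw,
             narrow_rpm = nRpm / k, body_rpm = bRpm / k,
             narrow_rank = nRank, body_rank = bRank)
}

#' Select the narrow and broad promoter lists
#'
#' Takes the top-N promoters by narrow-window rank and the top-N by
#' gene-body rank. Promoters appearing in both raw lists are assigned to
#' the list where their rank is smaller (a tie goes to narrow) and removed
#' from the other, yielding disjoint "unique" sets; with
#' \code{rule = "setdiff"} shared promoters are instead dropped from both.
#'
#' @param scores output of \code{\link{scorePromoters}}.
#' @param N list size; must be positive and at most the number of
#'   promoters.
#' @param rule \code{"rank"} (default smaller-rank assignment) or
#'   \code{"setdiff"}.
#' @return list with elements \code{narrow}, \code{broad} (disjoint unique
#'   sets) and \code{rawNarrow}, \code{rawBroad} (the plain top-N lists).
#' @export
selectTopProfiles <- function(scores, N, rule = c("rank", "setdiff")) {
  rule <- match.arg(rule)
  if (N <= 0) stop("N must be positive")
  if (N > nrow(scores)) stop("N exceeds the number of promoters")
  rawNarrow <- scores$gene_id[scores$narrow_rank <= N]
  rawBroad <- scores$gene_id[scores$body_rank <= N]
  both <- intersect(rawNarrow, rawBroad)
  if (rule == "setdiff") {
    narrow <- setdiff(rawNarrow, both)
    broad <- setdiff(rawBroad, both)
  } else {
    idx <- match(both, scores$gene_id)
    toNarrow <- both[scores$narrow_rank[idx] <= scores$body_rank[idx]]
    toBroad <- setdiff(both, toNarrow)
    narrow <- setdiff(rawNarrow, toBroad)
    broad <- setdiff(rawBroad, toNarrow)
  }
  list(narrow = narrow, broad = broad, rawNarrow = rawNarrow,
       rawBroad = rawBroad)
}

#' Meta-profile of net coverage across CpG islands and their shores
#'
#' Length-normalises each island to a fixed number of meta-bins and takes
#' the flanking shores (default 2 kb) in fixed bp bins, orienting each
#' island by its host promoter's strand so that "upstream shore" means the
#' 5' flank. Per-bp values are derived from the binned track and averaged
#' across islands; islands shorter than the number of meta-bins are
#' excluded with a message.
#'
#' @param net a \linkS4class{BinnedCoverage}.
#' @param islands \code{GRanges} islands; strand encodes host promoter
#'   orientation.
#' @param shoreWidth shore width in bp.
#' @param metaBins number of meta-bins the island body is rescaled to.
#' @param shoreBin shore bin width in bp.
#' @return data.frame with \code{segment} (upstream_shore / island /
#'   downstream_shore), \code{bin} (index within segment) and \code{mean}.
#' @export
islandShoreProfile <- function(net, islands, shoreWidth = 2000L,
                               metaBins = 20L, shoreBin = 50L) {
  bs <- net@binSize
  nShore <- as.integer(shoreWidth / shoreBin)
  perBp <- function(chr, from, to) {
    v <- net@values[[chr]]
    idx <- .binIndex(from:to, bs)
    ok <- idx >= 1L & idx <= length(v)
    out <- rep(NA_real_, length(idx))
    out[ok] <- v[idx[ok]]
    out
  }
  up <- matrix(NA_real_, 0, nShore); dn <- matrix(NA_real_, 0, nShore)
  isl <- matrix(NA_real_, 0, metaBins)
  excluded <- 0L
  for (i in seq_along(islands)) {
    if (width(islands)[i] < metaBins) { excluded <- excluded + 1L; next }
    chr <- as.character(seqnames(islands))[i]
    s <- start(islands)[i]; e <- end(islands)[i]
    left <- perBp(chr, s - shoreWidth, s - 1L)
    right <- perBp(chr, e + 1L, e + shoreWidth)
    body <- perBp(chr, s, e)
    ## rescale island body to metaBins by averaging within equal slices
    cuts <- findInterval(seq_along(body), seq(1, length(body) + 1,
                                              length.out = metaBins + 1),
                         rightmost.closed = TRUE)
    bodyMeta <- vapply(seq_len(metaBins),
                       function(b) mean(body[cuts == b], na.rm = TRUE),
                       numeric(1))
    shoreMean <- function(x) vapply(seq_len(nShore), function(b)
      mean(x[((b - 1L) * shoreBin + 1L):(b * shoreBin)], na.rm = TRUE),
      numeric(1))
    lm_ <- shoreMean(left); rm_ <- shoreMean(right)
    if (as.character(strand(islands))[i] == "-") {
      tmp <- rev(rm_); rm_ <- rev(lm_); lm_ <- tmp
      bodyMeta <- rev(bodyMeta)
    }
    up <- rbind(up, lm_); dn <- rbind(dn, rm_); isl <- rbind(isl, bodyMeta)
  }
  if (excluded > 0L)
    message(excluded, " island(s) shorter than ", metaBins,
            " bp excluded from the meta-profile")
  if (!nrow(isl)) stop("no island long enough for the meta-profile")
  data.frame(
    segment = rep(c("upstream_shore", "island", "downstream_shore"),
                  c(nShore, metaBins, nShore)),
    bin = c(seq_len(nShore), seq_len(metaBins), seq_len(nShore)),
    mean = c(colMeans(up, na.rm = TRUE), colMeans(isl, na.rm = TRUE),
             colMeans(dn, na.rm = TRUE)))
}

#' Promoter-anchored coverage matrix
#'
#' One row per gene, columns the net coverage bins from
#' \code{-upstream} to \code{+downstream} of the TSS, strand-oriented.
#' Genes whose window leaves the chromosome are dropped (row names record
#' the retained gene ids).
#'
#' @param net a \linkS4class{BinnedCoverage}.
#' @param genes \code{GRanges} gene models with \code{gene_id}.
#' @param upstream,downstream window extent in bp (default -3 kb/+20 kb).
#' @return numeric matrix with gene ids as row names.
#' @export
profileMatrix <- function(net, genes, upstream = 3000L,
                          downstream = 20000L) {
  bs <- net@binSize
  nUp <- as.integer(upstream / bs); nDn <- as.integer(downstream / bs)
  chrAll <- as.character(seqnames(genes))
  minus <- as.character(strand(genes)) == "-"
  tss <- ifelse(minus, end(genes), start(genes))
  rows <- list()
  for (i in seq_along(genes)) {
    v <- net@values[[chrAll[i]]]
    b0 <- .binIndex(tss[i], bs)
    idx <- if (minus[i]) (b0 + nUp):(b0 - nDn + 1L) else
      (b0 - nUp):(b0 + nDn - 1L)
    if (min(idx) < 1L || max(idx) > length(v)) next
    rows[[genes$gene_id[i]]] <- v[idx]
  }
  if (!length(rows)) stop("no gene fits the profile window")
  do.call(rbind, rows)
}

## k-means++ seeding: distance-proportional centre choice, fixed RNG state.
.kmeansPlusPlus <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  idx <- sample.int(n, 1L)
  centers[1L, ] <- x[idx, ]
  d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1L, prob = p)
    centers[j, ] <- x[idx, ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

#' Cluster promoters on their joint 5hmC/5mC profiles
#'
#' Standardises each row of the two mark matrices, concatenates them
#' column-wise, and runs k-means (k-means++ seeding, Lloyd iterations, at
#' most 300) under a fixed seed. Rows must be aligned across marks.
#'
#' @param mat5hmc,mat5mc row-aligned profile matrices (gene ids as row
#'   names).
#' @param k number of clusters (default 10); must not exceed the row
#'   count.
#' @param seed RNG seed for reproducible seeding.
#' @return list with \code{assignment} (named integer vector),
#'   \code{centers} and \code{sizes}.
#' @export
clusterJointProfiles <- function(mat5hmc, mat5mc, k = 10L, seed = 1L) {
  if (!identical(rownames(mat5hmc), rownames(mat5mc)))
    stop("mark matrices must be row-aligned")
  if (k > nrow(mat5hmc)) stop("k exceeds the number of promoters")
  std <- function(m) {
    mu <- rowMeans(m); s <- apply(m, 1, sd); s[s == 0] <- 1
    (m - mu) / s
  }
  x <- cbind(std(mat5hmc), std(mat5mc))
  set.seed(seed)
  centers <- .kmeansPlusPlus(x, k)
  centers <- centers + matrix(rnorm(length(centers), sd = 1e-9),
                              nrow(centers))  # guard duplicate seeds
  fit <- suppressWarnings(kmeans(x, centers = centers, iter.max = 300L,
                                 algorithm = "Lloyd"))
  list(assignment = setNames(fit$cluster, rownames(mat5hmc)),
       centers = fit$centers, sizes = fit$size)
}
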
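#' Beta value from channel intensities
#'
#' \code{beta = M / (U + M)}, with no stabilising offset. Records with
#' \code{M + U = 0} yield \code{NA} and are excluded downstream.
#'
#' @param M,U non-negative methylated / unmethylated channel intensities
#'   (vectorised).
#' @return numeric beta values in [0, 1] (NA where M + U = 0).
#' @examples
#' betaValue(c(500, 0, 300), c(500, 800, 100))
#' @export
betaValue <- function(M, U) {
  tot <- M + U
  ifelse(tot > 0, M / tot, NA_real_)
}

#' Filter intensity records on detection quality and probe flags
#'
#' Drops records with detection p-value at or above the threshold (strict:
#' exactly 0.05 is dropped at the default) and removes entirely any probe
#' flagged cross-reactive, SNP-containing, or on a sex chromosome.
#' Filtering is idempotent.
#'
#' @param records data.frame with \code{probe_id}, \code{sample_id},
#'   \code{M}, \code{U}, \code{detection_p}.
#' @param manifest \code{GRanges} probe manifest with \code{probe_id} and
#'   logical flags \code{cross_reactive}, \code{snp}, \code{sex_chrom};
#'   every record's probe must be present.
#' @param detectionAlpha detection threshold.
#' @return the retained records.
#' @export
filterProbes <- function(records, manifest, detectionAlpha = 0.05) {
  mf <- as.data.frame(mcols(manifest))
  miss <- setdiff(unique(records$probe_id), mf$probe_id)
  if (length(miss))
    stop("probe(s) absent from manifest: ", paste(head(miss, 5), collapse = ", "))
  bad <- mf$probe_id[mf$cross_reactive | mf$snp | mf$sex_chrom]
  keep <- !(records$probe_id %in% bad) & records$detection_p < detectionAlpha
  records[keep, , drop = FALSE]
}

## logit2 transform between beta and M-value scales.
.beta2m <- function(b, eps = 1e-6) {
  b <- pmin(pmax(b, eps), 1 - eps)
  log2(b / (1 - b))
}
.m2beta <- function(m) 2^m / (1 + 2^m)

## Density modes of M-values below and above 0 (Silverman bandwidth).
.mModes <- function(m) {
  d <- density(m, bw = "nrd0", n = 1024)
  lo <- d$x < 0; hi <- d$x > 0
  if (!any(lo) || !any(hi)) return(NULL)
  uPk <- d$x[lo][which.max(d$y[lo])]
  mPk <- d$x[hi][which.max(d$y[hi])]
  if (max(d$y[lo]) <= 0 || max(d$y[hi]) <= 0) return(NULL)
  c(u = uPk, m = mPk)
}

#' Peak-based correction of Infinium type I/II bias
#'
#' Per sample, transforms betas to M-values, locates the unmethylated
#' (mode below M = 0) and methylated (mode above 0) density peaks of each
#' design type, and linearly rescales the type II M-values so its two
#' peaks coincide with type I's; type I values are returned untouched and
#' output betas are clipped to [0, 1]. When fewer than two modes are
#' detectable for a sample (or the rescaling slope is not positive) the
#' correction is skipped for that sample with a warning.
#'
#' @param betas numeric matrix, probes x samples.
#' @param designTypes character vector ("I"/"II") parallel to rows; at
#'   least 50 probes of each type are required.
#' @return corrected beta matrix of the same shape.
#' @export
peakBasedCorrection <- function(betas, designTypes) {
  stopifnot(length(designTypes) == nrow(betas))
  isII <- designTypes == "II"
  if (sum(isII) < 50L || sum(!isII) < 50L)
    stop("need at least 50 probes of each design type")
  out <- betas
  for (j in seq_len(ncol(betas))) {
    ok <- !is.na(betas[, j])
    m1 <- .beta2m(betas[ok & !isII, j])
    m2 <- .beta2m(betas[ok & isII, j])
    p1 <- .mModes(m1); p2 <- .mModes(m2)
    if (is.null(p1) || is.null(p2) || p2[["m"]] - p2[["u"]] <= 0) {
      warning("sample ", j, ": fewer than two density modes; correction skipped")
      next
    }
    a <- (p1[["m"]] - p1[["u"]]) / (p2[["m"]] - p2[["u"]])
    if (a <= 0) {
      warning("sample ", j, ": non-positive rescale slope; correction skipped")
      next
    }
    mm <- .beta2m(betas[ok & isII, j])
    out[ok & isII, j] <- pmin(pmax(.m2beta((mm - p2[["u"]]) * a + p1[["u"]]),
                                   0), 1)
  }
  out
}

#' Channel log-ratio with delta-method standard error
#'
#' \code{log2((M + a) / (U + a))} with stabilising offset \code{a}
#' (default 100; 0 disables). The standard error assumes intensity
#' variance proportional to intensity (\code{var(X) = X / dispersion}), so
#' by the delta method
#' \code{se^2 = (M/(M+a)^2 + U/(U+a)^2) / (dispersion * ln(2)^2)}.
#'
#' @param M,U non-negative channel intensities (vectorised).
#' @param offset stabilising offset \code{a}.
#' @param dispersion intensity dispersion \code{phi}.
#' @return data.frame with \code{log_ratio} and \code{se}.
#' @examples
#' muLogRatio(1000, 1000)$log_ratio  # 0
#' @export
muLogRatio <- function(M, U, offset = 100, dispersion = 1) {
  lr <- log2((M + offset) / (U + offset))
  se <- sqrt((M / (M + offset)^2 + U / (U + offset)^2) /
               (dispersion * log(2)^2))
  data.frame(log_ratio = lr, se = se)
}

## Moment-matching fit of the scaled-F prior for residual variances:
## s2 ~ s0^2 * F(d, d0). Returns c(d0, s02); d0 = Inf when the observed
## spread of s2 is no wider than chi-square sampling noise allows.
.fitFMoments <- function(s2, d) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  m <- mean(s2); v <- var(s2)
  r <- v / m^2
  ## under a pure chi-square (no prior spread) r = 2/d, so excess spread
  ## requires r * d > 2
  if (!is.finite(r) || r * d <= 2) {
    ## no excess spread: effectively infinite prior df
    return(c(d0 = Inf, s02 = m))
  }
  d0 <- (2 * d - 4 + 4 * r * d) / (r * d - 2)
  if (d0 <= 4) d0 <- 4.01  # keep the matched moments finite
  s02 <- m * (d0 - 2) / d0
  c(d0 = d0, s02 = s02)
}

#' Weighted, moderated paired differential methylation
#'
#' Per probe, fits the matched tumour - normal difference of the channel
#' log-ratios by weighted least squares with weights \code{1/se^2}
#' (unweighted when no standard errors are supplied), then moderates the
#' residual variances with an empirical-Bayes squeeze: the prior
#' \code{(d0, s0^2)} is fitted by moment-matching the scaled-F
#' distribution of the per-probe variances, the posterior variance is
#' \code{(d0 s0^2 + d s^2) / (d0 + d)}, and the moderated t is referred to
#' a t distribution on \code{d0 + d} degrees of freedom. Probes are
#' labelled \code{gain}/\code{loss} by the sign of the mean paired beta
#' difference when \code{p < alpha}, and \code{none} otherwise.
#'
#' @param values numeric matrix probes x samples (channel log-ratios, or
#'   betas for an unweighted analysis); column names are sample ids.
#' @param se optional matrix of standard errors matching \code{values}.
#' @param pairing data.frame with \code{normal_id} and \code{tumour_id};
#'   at least 2 pairs.
#' @param betas optional beta matrix used for the reported mean paired
#'   beta difference and the gain/loss sign (defaults to \code{values}).
#' @param alpha raw p-value threshold for gain/loss calls.
#' @param priorDf force the prior degrees of freedom \code{d0} (0 gives
#'   the ordinary weighted paired t); \code{NULL} fits it from the data.
#' @return data.frame with \code{probe_id}, \code{mean_beta_diff},
#'   \code{estimate}, \code{t}, \code{df}, \code{p}, \code{label};
#'   attributes \code{d0} and \code{s02} record the fitted prior.
#' @export
weightedDiffMeth <- function(values, se = NULL, pairing, betas = NULL,
                             alpha = 0.01, priorDf = NULL) {
  if (nrow(pairing) < 2L) stop("need at least 2 matched pairs")
  nid <- as.character(pairing$normal_id)
  tid <- as.character(pairing$tumour_id)
  if (!all(c(nid, tid) %in% colnames(values)))
    stop("pairing refers to samples absent from the value matrix")
  d <- values[, tid, drop = FALSE] - values[, nid, drop = FALSE]
  np <- ncol(d)
  w <- if (is.null(se)) matrix(1, nrow(d), np) else
    1 / (se[, tid, drop = FALSE]^2 + se[, nid, drop = FALSE]^2)
  ## pairs with a missing value (e.g. detection-filtered records) drop out
  ## of that probe's fit with weight 0
  miss <- is.na(d) | is.na(w)
  w[miss] <- 0; d[miss] <- 0
  npPer <- rowSums(!miss)
  if (any(npPer < 2L))
    warning(sum(npPer < 2L), " probe(s) with fewer than 2 complete pairs")
  sw <- rowSums(w)
  est <- rowSums(w * d) / sw
  resid <- d - est
  resid[miss] <- 0
  s2 <- rowSums(w * resid^2) / pmax(npPer - 1L, 1L)
  dfRes <- pmax(npPer - 1L, 1L)
  if (is.null(priorDf)) {
    fit <- .fitFMoments(s2, stats::median(dfRes))
    d0 <- fit[["d0"]]; s02 <- fit[["s02"]]
  } else {
    d0 <- priorDf
    s02 <- if (d0 > 0) mean(s2[is.finite(s2)]) else 0
  }
  s2post <- if (is.infinite(d0)) rep(s02, length(s2)) else
    (d0 * s02 + dfRes * s2) / (d0 + dfRes)
  tstat <- est / sqrt(s2post / sw)
  tstat[est == 0 & !is.finite(tstat)] <- 0  # 0/0: no effect, no variance
  dfTot <- d0 + dfRes
  p <- 2 * pt(-abs(tstat), df = dfTot)
  bmat <- if (is.null(betas)) values else betas
  bDiff <- rowMeans(bmat[, tid, drop = FALSE] - bmat[, nid, drop = FALSE],
                    na.rm = TRUE)
  label <- ifelse(!is.na(p) & p < alpha,
                  ifelse(bDiff > 0, "gain", "loss"), "none")
  out <- data.frame(probe_id = rownames(values), mean_beta_diff = bDiff,
                    estimate = est, t = tstat, df = dfTot, p = p,
                    label = label, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

## Finite-population mean/variance of the mean rank of m draws without
## replacement from the (tie-adjusted) rank vector r.
.meanRankNull <- function(r, m) {
  n <- length(r)
  mu <- mean(r)
  sig2 <- sum((r - mu)^2) / n
  c(mean = mu, var = sig2 / m * (n - m) / (n - 1))
}

#' Mean-rank gene-set test
#'
#' Tests whether the probes in a set rank higher (or lower) in a statistic
#' than expected for a random set of the same size: the p-value is the
#' probability that a random same-size subset has mean rank at least (or
#' at most) the observed mean rank. Computed by exact enumeration when
#' both the set and its complement have at most 10 members, otherwise by
#' the Wilcoxon rank-sum normal approximation with tie-adjusted ranks and
#' continuity correction.
#'
#' @param statistics numeric vector of per-probe statistics (the ranking
#'   variable).
#' @param inSet logical vector (or index vector) marking set members; the
#'   set must be non-empty and a proper subset.
#' @param alternative \code{"greater"} (set mean rank higher),
#'   \code{"less"}, or \code{"two.sided"}.
#' @return the p-value.
#' @export
geneSetRankTest <- function(statistics, inSet,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(statistics)
  if (!is.logical(inSet)) inSet <- seq_len(n) %in% inSet
  m <- sum(inSet)
  if (m == 0L || m == n) stop("set must be non-empty and a proper subset")
  r <- rank(statistics)
  obs <- mean(r[inSet])
  if (m <= 10L && (n - m) <= 10L) {
    sets <- combn(n, m)
    means <- colMeans(matrix(r[sets], nrow = m))
    eps <- 1e-9
    pg <- mean(means >= obs - eps)
    pl <- mean(means <= obs + eps)
  } else {
    nul <- .meanRankNull(r, m)
    cc <- 1 / (2 * m)  # mean-rank granularity
    sdv <- sqrt(nul[["var"]])
    pg <- pnorm((obs - nul[["mean"]] - cc) / sdv, lower.tail = FALSE)
    pl <- pnorm((obs - nul[["mean"]] + cc) / sdv)
  }
  switch(alternative, greater = pg, less = pl,
         two.sided = min(1, 2 * min(pg, pl)))
}

#' Two-sided Wilcoxon rank-sum comparison
#'
#' Rank-sum test of two groups: exact enumeration of the rank-sum
#' distribution (over all group assignments of the tie-adjusted pooled
#' ranks) when the pooled size is at most 12, otherwise a normal
#' approximation whose variance is the exact finite-population variance of
#' the observed ranks (which incorporates ties), with continuity
#' correction. When all pooled values are tied the p-value is 1.
#'
#' @param groupA,groupB non-empty numeric vectors.
#' @return list with \code{statistic} (rank sum of group A) and \code{p}
#'   (two-sided).
#' @examples
#' rankSumCompare(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
rankSumCompare <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  if (nA == 0L || nB == 0L) stop("both groups must be non-empty")
  pooled <- c(groupA, groupB)
  r <- rank(pooled)
  W <- sum(r[seq_len(nA)])
  n <- nA + nB
  if (length(unique(pooled)) == 1L)
    return(list(statistic = W, p = 1))
  if (n <= 12L) {
    sets <- combn(n, nA)
    sums <- colSums(matrix(r[sets], nrow = nA))
    eps <- 1e-9
    pg <- mean(sums >= W - eps)
    pl <- mean(sums <= W + eps)
    p <- min(1, 2 * min(pg, pl))
  } else {
    mu <- nA * mean(r)
    sig2 <- nA * (sum((r - mean(r))^2) / n) * (n - nA) / (n - 1)
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(statistic = W, p = p)
}
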
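---
title: "Promoter 5hmC profiling and methylation-resistance analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter 5hmC profiling and methylation-resistance analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcprofiler)
```

## The scientific question

5-hydroxymethylcytosine (5hmC) is the first oxidation product of
5-methylcytosine (5mC) produced by the TET dioxygenases. In normal colon
epithelium, 5hmC accumulates at the promoters and gene bodies of active
genes; in tumours it is globally depleted. The analysis implemented here
asks how the 5hmC state of a promoter in *normal* tissue relates to its
DNA-methylation fate in a matched *tumour*: promoters that carry 5hmC in
normal tissue should resist hypermethylation in cancer (and if anything
lose methylation), whereas promoters lacking 5hmC should be the ones prone
to methylation gain. Two orthogonal overlays complete the picture: ChIP
peaks of TET2 in a colorectal cancer cell line (TET2-bound promoters
should be depleted of methylation gain), and the set of promoters that are
bivalently marked (H3K4me3 + H3K27me3) in embryonic stem cells, which are
known to be predisposed to cancer hypermethylation.

The package implements this as five analysis layers plus a synthetic data
generator, so the whole chain is testable end to end without any external
download:

1. **Annotation** — CpG-island detection, promoter CpG-content classes
   (HCP/ICP/LCP), strand-aware promoter windows, probe-to-promoter
   assignment.
2. **hmeDIP coverage** — reads-per-million normalisation, input
   subtraction, TSS metagenes, genomic feature distribution, probe-window
   read counting.
3. **Promoter profiles** — "narrow" vs "broad" 5hmC profile ranking,
   island/shore meta-profiles, joint 5hmC/5mC k-means profile clustering.
4. **Methylation arrays** — beta values, probe filtering, peak-based type
   I/II correction, channel log-ratios with delta-method errors, weighted
   moderated differential methylation, rank tests.
5. **Integration** — 5hmC-high/low locus cross-tabulation, TET2 overlap
   depletion, three-way bivalency Venn analysis, persistent-5hmC
   cross-tabulation, and the hmC share of the bisulfite signal.

## Models and procedures

### hmeDIP-seq quantification

Immunoprecipitation coverage is quantified as reads per million mapped
reads (RPM) on a fixed bin grid (default 50 bp), and the matching input
library is subtracted bin-wise. Negative net values are retained: the
subtraction has no clamping rule, and every downstream use (ranking,
averaging) is unaffected by the sign convention. Two counting modes
coexist deliberately: coverage tracks count a read into every bin it
overlaps (smooth profiles), while all count statistics (feature
distribution, promoter scores, probe windows) assign each read once, by
its midpoint, so totals are conserved and fractions sum to one exactly.

Promoter 5hmC content is measured in two windows: the *narrow* window
from 1 kb upstream to 0.5 kb downstream of the TSS, and the *gene body*
from TSS to TTS. Ranking all genes by each count and taking the top N of
each list yields the narrow and broad promoter profile classes; genes
appearing in both raw lists are assigned to the list where they rank
better (ties go to narrow), producing disjoint "unique" lists. The
de-duplication rule is a declared choice (`uniqueRule = "rank"`), with a
plain set-difference variant available, because published unique-list
counts do not state the rule.

For array integration, hmeDIP reads from the normal samples are counted
in 200 bp windows centred on each array probe
(`countReadsInProbeWindows`). Each sample is RPM-scaled before averaging;
the pooling rule is config-switchable to raw summed counts, since the
combination rule for multiple normal libraries is another genuinely open
choice.

### Infinium-style methylation processing

Beta values are `M/(U+M)` with no offset. Records failing detection
(p >= 0.05, strictly) are dropped, and probes flagged cross-reactive,
SNP-containing, or on sex chromosomes are removed entirely.

Design type I and II probes have systematically different beta
distributions. The peak-based correction transforms betas to M-values,
finds each type's unmethylated (mode below M = 0) and methylated (mode
above 0) density peaks with a Gaussian kernel (Silverman bandwidth), and
applies the affine map on M-values that sends the type II peak pair onto
the type I pair, back-transforming to beta and clipping to [0, 1]. A
single affine map anchors both peaks exactly and is monotone, so
within-type rank order is preserved; type I values are returned untouched.
When a sample's density lacks one of the two modes the correction is
skipped for that sample with a warning.

Differential methylation uses the channel log-ratio
`log2((M+a)/(U+a))` with stabilising offset `a = 100` (0 disables; the
published formula has no offset, so it is exposed). The standard error
follows the delta method under intensity variance proportional to
intensity: `se^2 = (M/(M+a)^2 + U/(U+a)^2) / (phi * ln(2)^2)` with
dispersion `phi` configurable. Matched tumour-normal differences are fit
per probe by weighted least squares (weights `1/se^2`), and residual
variances are moderated empirically: the prior `(d0, s0^2)` of the
scaled-F model `s^2 ~ s0^2 F(d, d0)` is fitted by moment matching (mean
and variance of the observed `s^2`), the posterior variance is
`(d0 s0^2 + d s^2)/(d0 + d)`, and the moderated t is referred to
`d0 + d` degrees of freedom. When the observed spread of `s^2` does not
exceed chi-square sampling noise (`var/mean^2 <= 2/d`) the prior is
effectively infinite and the common variance is used. Probes with
`p < 0.01` (the threshold used for the gain/loss scatter classification)
are labelled gain or loss by the sign of the mean paired beta
difference; no magnitude floor is applied.

Group comparisons use a two-sided Wilcoxon rank-sum test: exact
enumeration of the rank-sum distribution when the pooled size is at most
12 (ties handled by enumerating the midranks), otherwise a normal
approximation whose variance is the exact finite-population variance of
the observed ranks — which is the tie correction — with continuity
correction. The gene-set test is the mean-rank analogue: exact when both
the set and complement have at most 10 members, normal otherwise.

### Integration statistics

The top-N probes by 5hmC probe-window score form the 5hmC-high set, the
bottom-N (zeros, i.e. undetected, first) the 5hmC-low set. Within each
set, the differential-methylation labels are cross-tabulated into
gain/loss proportions among significantly changed probes. TET2 target
promoters are those whose TSS +/- 1 kb window overlaps at least one peak.
The overlap between methylation-gain promoters and TET2 targets is tested
for depletion under a binomial null: each of the |A| gain promoters falls
in the target set with probability |B|/n, and the one-sided p-value is
`P(Bin(|A|, q) <= k)`. The binomial form mirrors the published test; a
hypergeometric variant (sampling without replacement) is provided because
the null's sampling scheme is not stated. The bivalency analysis reports
all seven regions of the 5hmC/bivalent/gain Venn decomposition plus the
two headline fractions (bivalent share of gain promoters; bivalent share
of 5hmC promoters).

Because bisulfite conversion cannot distinguish 5mC from 5hmC, a small
part of array "methylation" is actually hydroxymethylation. Given global
modification percentages (as from LC-MS), the contaminating share is
`pct_hmC / (pct_hmC + pct_mC)`; with the generator defaults (0.118% hmC,
4.8% mC in normal; tumour hmC scaled by 0.3) this gives about 2.4% in
normal and 0.7% in tumour tissue.

## The synthetic cohort generator

`simulateCohort()` produces a fully self-contained cohort with known
truth. Its defaults define the package's study conditions:

* **Genome and genes** — one 5 Mb chromosome carrying 300 non-overlapping
  genes (2-8 kb) on both strands. Sequence comes from a two-regime
  sampler: a CpG-depleted background (iid bases, GC 0.40, 92% of CpG
  dinucleotides broken, so plain promoters classify LCP in every 500 bp
  window) and CpG-rich segments planted at marked promoters - a high-CpG
  regime (GC 0.6, obs/exp near 1, 1.2 kb) at broad promoters and an
  intermediate regime (0.7 kb, 40% CpG broken) at narrow promoters,
  echoing the observed association of broad profiles with HCP and narrow
  with ICP promoters.
* **Promoter classes** — 100 narrow / 100 broad / 100 unmarked.
* **hmeDIP reads** — 60,000 fixed-length 50 bp reads per IP sample (5
  normal, 4 tumour) plus one input per tissue. Read midpoints are drawn
  from a mixture: 30% uniform background and the rest split equally among
  marked promoters (roughly 200 enrichment reads each). Narrow promoters
  use two truncated-Gaussian flanking kernels inside the -1 kb/+0.5 kb
  window with a depleted central bin (no midpoints within 60 bp of the
  TSS), reproducing the characteristic TSS dip; broad promoters use a
  uniform gene-body component. Tumour samples scale every enrichment
  weight by `tumourScale = 0.3` and return the displaced mass to the
  background - the antibody pulls down a fixed library amount - so the
  input-subtracted promoter RPM ratio between tumour and normal equals
  the scale factor in expectation. Fragment-length modelling, duplicates
  and sequencing errors are deliberately out of scope.
* **Arrays** — 2 probes per gene within 800 bp of the TSS, 17 matched
  normal/tumour pairs. A probe is a 5hmC-high locus when its 200 bp
  window can catch its promoter's enrichment (inside the narrow kernel
  support, or overlapping the gene body for broad genes); otherwise it is
  5hmC-low, even at a marked gene - this matches how high/low loci are
  defined operationally, by local read content. Normal betas are drawn
  per category: high loci intermediate (N(0.40, 0.10) truncated), low
  loci a 70/30 mixture of low (N(0.12, 0.06)) and methylated
  (N(0.85, 0.06)) states; the methylated component gives each sample the
  bimodal density the peak-based correction requires. Planted changes
  shift tumour betas by +/-0.25 at per-category rates - gain 5% / loss
  20% among high loci (4:1 loss-dominant) and gain 13% / loss 10% among
  low loci (1.3:1 gain-dominant) - chosen to reproduce the reciprocal
  pattern at its published strength. Intensities are
  `M = round(T * beta_obs)`, `U = T - M` with `T ~ N(2000, 100)`; type II
  betas are first compressed toward 0.5 by factor 0.8; detection failures
  are independent per record at rate 0.01.
* **Peaks and bivalency** — TET2 targets are drawn from marked promoters
  carrying no planted gain probe (the planted exclusion that the
  depletion analysis must detect), each receiving one or two peaks
  entirely within 1 kb of the TSS. The bivalent list is assembled so 65%
  of gain-prone promoters and 30% of marked promoters are bivalent.

Everything is deterministic given the master seed: sub-generators run
under fixed derived seeds, so identical configs give byte-identical
cohorts, and `runPipeline` twice with one seed writes identical summary
JSON.

### What the generator does and does not emulate

The generator reproduces the *structure* of the study data - enrichment
shapes, matched-pair design, design-type bias, detection failures,
planted reciprocal effects, exclusion and overlap fractions - so that
passing tests demonstrate the pipeline recovers planted truth through the
full read/intensity representation. It does not emulate biological
variance components (patient heterogeneity, batch effects, copy number,
repeat content), and the genome is three orders of magnitude denser in
reads per bp than a human study; recovery rates on real cohorts will be
lower, and the published cohort-level counts are not reproduction
targets. One visible scale effect: at 60,000 reads on 5 Mb, uniform
background alone exceeds the default 1-RPM persistence floor in every
200 bp window, so the persistent-5hmC set covers all promoters on the
default cohort; the statistic and its reporting are unchanged.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `narrowUpstream`/`narrowDownstream` | 1000/500 bp | promoter window for narrow-profile counting |
| `probeWindow` | 200 bp | read-count window around each array probe |
| `topN` | 3000 | 5hmC-high/low locus list size (27k-array scale) |
| `profileN` | 100 | narrow/broad list size (default-cohort scale) |
| `tet2Flank` | 1000 bp | TSS flank for peak-to-promoter assignment |
| `alpha` | 0.01 | raw p threshold for gain/loss calls |
| `maxProbeTssDistance` | 1499 bp | inclusive probe assignment bound |
| `binSize` | 50 bp | coverage grid |
| `metageneFlank` | 3000 bp | TSS metagene half-width |
| `clusterK` | 10 | joint-profile clusters |
| `shoreWidth` | 2000 bp | island shore extent |
| `offset` | 100 | log-ratio stabilising offset (0 disables) |
| `detectFloor` | 1 RPM | tumour 5hmC persistence floor |

`topN = 3000` assumes an array of about 27,000 loci, where each tail is
roughly 11% of the platform. When the configured value does not fit the
cohort (2 x topN exceeding the retained probes), `runPipeline` rescales
it to that same 11% tail fraction, so "high" and "low" remain genuine
distribution tails rather than overlapping halves. Benjamini-Hochberg
adjustment of the differential p-values is available but off by default;
the gain/loss classification threshold is a raw p-value by design.

## Numerical choices and degenerate inputs

* Observed/expected CpG with zero C or G counts is defined as 0, which
  forces LCP rather than dividing by zero.
* Probe-to-promoter ties (equidistant TSSs) break by lexicographic gene
  id; rank ties in promoter scoring break by gene id; both make reruns
  reproducible.
* The probe-TSS distance bound is inclusive of 1,499 bp and exclusive of
  1,500 bp.
* Probe windows are half-open: a midpoint exactly at `pos + window/2` is
  not counted.
* Reads with fewer than 2 complete pairs after detection filtering keep
  weight-0 placeholders and are labelled `none`.
* `t = 0/0` (zero effect, zero variance) is defined as 0 with p = 1.
* k-means uses k-means++ seeding under a fixed seed with a tiny jitter
  guard against duplicate seed points, then Lloyd iterations (max 300).
  The clustering is a declared stand-in for the heatmap-tool clustering
  of the original analysis and is not expected to reproduce any
  particular published cluster structure.
* Empty promoter windows (upstream = downstream = 0), empty read sets,
  `k > n`, sets equal to their universe, and a zero denominator in the
  hmC fraction are all rejected with explicit errors.

## Problem sizes used by the tests

The test suite runs the full pipeline on the default 300-gene / 5 Mb /
600-probe cohort (about half a minute), the reciprocal-pattern check on a
1,500-gene / 15 Mb cohort with 6,000 probes and 20 re-drawn intensity
replicates, the calibration check on 10,000 null probes with 17 pairs,
and the classification oracles on 1,000 random promoter contexts. These
sizes were chosen so each property is measured with comfortable
statistical power while the whole suite stays quick to run on a laptop.

## Known limitations

* One TSS per gene; no transcript isoforms.
* No BAM input in the core contract; reads are consumed as BED-like
  intervals (convert upstream with standard tools).
* Island detection is a Gardiner-Garden-style stand-in, not a copy of any
  genome annotation release.
* Channel metadata (red/green) is accepted for stratified analysis but no
  channel-specific modelling beyond stratification is implemented.
* The published cohort-level gene lists and counts are descriptive
  context, not reproduction targets; they derive from patient data that
  is not redistributed here.
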
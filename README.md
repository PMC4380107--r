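# hmcprofiler

Integrative analysis of promoter 5-hydroxymethylcytosine (5hmC) and DNA
methylation change in matched normal/tumour cohorts.

## The problem

5hmC, the oxidation product of 5-methylcytosine (5mC) generated by the
TET enzymes, accumulates at the promoters and bodies of active genes in
differentiated colon epithelium and is globally depleted in tumours. The
question this package operationalises: **does 5hmC marking of a promoter
in normal tissue predict its methylation fate in cancer?** The analysis
combines three data types over a shared promoter universe:

* **hmeDIP-seq** read sets (IP + input) quantifying where 5hmC sits in
  normal and tumour tissue;
* **Infinium-style methylation arrays** (M/U channel intensities) for
  matched normal/tumour pairs, giving per-CpG beta values
  `beta = M/(U + M)` and paired gain/loss calls;
* **ChIP peak sets and gene lists** (TET2 binding, embryonic-stem-cell
  bivalent promoters) for overlap statistics.

The core statistics, in the field's standard notation:

* promoter 5hmC content ranked in the narrow window (TSS −1 kb to
  +0.5 kb) and the gene body (TSS to TTS), defining disjoint "narrow" and
  "broad" promoter profiles;
* reads per million (RPM) coverage, input-subtracted, for TSS metagenes
  and CpG-island/shore meta-profiles;
* weighted moderated paired t statistics on channel log-ratios
  `log2((M+a)/(U+a))` with delta-method standard errors and an
  empirical-Bayes variance squeeze
  `s2_post = (d0*s0^2 + d*s^2)/(d0 + d)` (prior fitted by moment
  matching), labelling probes gain/loss at raw `p < 0.01`;
* peak-based correction mapping design-type II M-value density peaks onto
  type I's;
* cross-tabulation of gain/loss within the top/bottom-ranked 5hmC loci;
* a one-sided binomial depletion test `P(Bin(|A|, |B|/n) <= k)` for the
  overlap of methylation-gain promoters with TET2 targets;
* three-way Venn decomposition of 5hmC / bivalent / methylation-gain
  promoter sets;
* the hmC share of the bisulfite signal, `pct_hmC/(pct_hmC + pct_mC)`.

A deterministic synthetic-cohort generator (`simulateCohort`) emulates
the full data structure — enrichment shapes with the TSS dip, the global
tumour 5hmC reduction, design-type beta bias, planted reciprocal
methylation changes, TET2 exclusion and bivalency overlap structure —
with a truth sidecar, so every stage is testable end to end.

## Worked example

```r
library(hmcprofiler)

cfg <- SimConfig(seed = 1)       # 5 Mb, 300 genes, 17 array pairs
res <- runPipeline(cfg)
s <- res$summary

s$profile_balanced_accuracy
#> [1] 1
unlist(s$crosstab_high[c("n_significant", "prop_gain", "prop_loss")])
#> n_significant     prop_gain     prop_loss
#>    18.0000000     0.2777778     0.7222222
unlist(s$crosstab_low[c("n_significant", "prop_gain", "prop_loss")])
#> n_significant     prop_gain     prop_loss
#>          15.0           0.6           0.4
s$tet2_overlap$p_depletion
#> [1] 1.471932e-06
unlist(s$venn[c("frac_gain_bivalent", "frac_hmc_bivalent")])
#> frac_gain_bivalent  frac_hmc_bivalent
#>          0.6226415          0.3000000
unlist(s$hmc_fraction_of_bisulfite)
#>      normal      tumour
#> 0.023993493 0.007321008
```

Reading the output: the planted narrow/broad promoter profiles are
recovered perfectly from the simulated reads (balanced accuracy 1.0).
Among array loci ranked 5hmC-high in normal tissue, significant
methylation changes are loss-dominated (72% loss vs 28% gain), while
5hmC-low loci are gain-dominated (60% vs 40%) — the reciprocal pattern
the analysis is designed to expose. Methylation-gain promoters barely
overlap TET2-target promoters (binomial depletion p ≈ 1.5e-6), 62% of
gain promoters and 30% of 5hmC promoters are bivalent, and about 2.4%
(normal) / 0.7% (tumour) of the apparent bisulfite methylation signal is
attributable to 5hmC.

`runPipeline` also accepts an `HmcCohort` object or a directory written
by `writeCohort()` (FASTA genome, BED reads/peaks, TSV gene models,
manifest and intensities, JSON truth sidecar, YAML config), and writes a
deterministic JSON summary via `summaryJson=`.

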
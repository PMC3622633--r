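---
title: "Empirical DMR calling: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical DMR calling: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmrseg)
```

## The problem

Enrichment-based bisulfite protocols (RRBS, ERRBS and relatives) measure DNA
methylation at single-base resolution, but concentrate coverage in CpG-rich
sequence around restriction sites. Per-site differential tests find
differentially methylated cytosines (DMCs); biological regulation, however,
often acts through groups of neighbouring CpGs. `dmrseg` turns a per-CpG
differential table (chromosome, position, strand, methylation difference in
percentage points, p- and q-value) into differentially methylated *regions*
(DMRs), with an empirically determined region boundary distance, content
filters, a dependence-adjusted region p-value, and annotation.

Throughout, the methylation difference convention is **treatment minus
control**: a hypermethylated DMR has positive mean difference.

## The gap mixture and the weighted cost

Because coverage is enriched, covered CpGs come in clusters. The log2
distances between adjacent covered CpGs on a chromosome are therefore
bimodal: a small-gap mode from *regional* CpGs (within a cluster) and a
large-gap mode from *boundary* CpGs (between clusters). When input is not
destranded, the reverse-complement CpG on the opposite strand sits exactly
1 bp away and produces a spike at log2 distance 0; these gaps say nothing
about region boundaries and are removed before fitting (`compute_gap_sample`
drops gaps ≤ 1 bp and counts them).

The retained sample is fit with a two-component normal mixture

$$F(x) = \lambda_1\,N(\mu_1, \sigma_1^2) + \lambda_2\,N(\mu_2, \sigma_2^2),
\qquad \lambda_1 + \lambda_2 = 1,$$

by expectation maximisation (`fit_bimodal_em`). Components are relabelled so
that $\mu_1 < \mu_2$; the first component describes regional gaps and, in
enrichment data, has by far the larger mixing proportion.

Choosing a single separation point $x$ misclassifies some gaps from each
component. Because the two populations are very unbalanced, the cut is
placed by minimising the *mixing-weighted* misclassification cost

$$C(x) = \lambda_1 P_1(X \ge x) + \lambda_2 P_2(X \le x),$$

so each population is penalised in proportion to its abundance
(`mixture_cost`). The minimiser satisfies the stationarity condition
$\lambda_1 f_1(\hat x) = \lambda_2 f_2(\hat x)$ — the weighted component
densities cross at the optimum. `optimize_cutoff` searches the observed
range of retained log2 distances with successive parabolic interpolation
(`stats::optimize`) and then polishes the result with Newton steps on the
stationarity condition, which makes the returned $\hat x$ accurate to well
below the $10^{-6}$ optimiser tolerance. The base-pair cutoff is
$D = \mathrm{round}(2^{\hat x})$, floored at 2 bp. On ERRBS-like data $D$
typically lands in the 150–200 bp range.

```{r fit-example}
sim <- simulate_methylome(synth_config(seed = 1, n_cpgs = 40000L,
                                       n_dmrs = 12L))
gaps <- compute_gap_sample(sim$cpgs)
fit <- fit_bimodal_em(gaps)
cutoff <- optimize_cutoff(fit, gaps)
cutoff
```

## Segmentation and the three filters

`segment_regions` starts a new region whenever the distance to the previous
CpG on the same chromosome is *strictly greater* than $D$ (a gap exactly
equal to $D$ does not split — the strictness direction is a convention this
package fixes and documents, since either reading is defensible). Candidate
regions then pass three independent, adjustable filters
(`filter_regions`): at least 1 DMC, at least 3 CpGs, and absolute mean
methylation difference strictly greater than 20 percentage points. The mean
difference is the unweighted arithmetic mean over member CpGs; the region
direction (hyper/hypo) is its sign, and no tie is possible after the 20%
filter. The DMC definition defaults to q < 0.01 and |difference| ≥ 25
percentage points, the common convention of upstream per-site callers; both
thresholds are exposed (`dmc_qvalue`, `dmc_diff`).

## Region significance

Neighbouring CpGs are correlated, so member p-values cannot be combined as
if independent. `estimate_acf` bins each chromosome into 100-bp segments
(adjustable), averages the probit-transformed p-values
$z = \Phi^{-1}(1-p)$ per bin, and estimates the Pearson autocorrelation at
lags of 1–10 bins. `region_correlation_matrix` maps that ACF onto the
member-CpG pairs of a region via $\sigma_{ij} = \rho[\lceil d_{ij} /
\text{bin} \rceil]$ (0 beyond the largest lag), flooring the spectrum at 0
if the patched matrix is not positive semidefinite. The region p-value is
the dependence-adjusted Stouffer–Liptak combination

$$T = \frac{\sum_i z_i}{\sqrt{\sum_{ij} \sigma_{ij}}}, \qquad
p_{\text{region}} = 1 - \Phi(T),$$

with p-values clamped to $[10^{-15}, 1-10^{-15}]$ to keep $z$ finite.
Benjamini–Hochberg correction across the surviving regions gives q-values.

Two ambiguities are resolved as follows, both switchable:

* **Which members to combine.** All member CpGs by default
  (`combine = "all"`); combining only DMCs (`combine = "dmc-only"`) is
  anti-conservative because it selects the smallest p-values, but is offered
  for comparability.
* **Which ACF drives the adjustment.** The p-value ACF (probit scale) by
  default; the methylation-difference ACF can be computed with
  `estimate_acf(..., source = "meth_diff")` as a diagnostic or used via
  `acf_source`.

Filters are applied *before* combination and correction, so the FDR is
controlled over the regions actually tested.

## Annotation

`derive_gene_parts` splits refFlat transcripts into promoter (TSS ± 1000 bp
by default, strand-aware — "promoter" has no universal definition, and this
window matches the common default of the surrounding toolchain), 5'/3' UTR,
CDS and introns; for every coding transcript the UTRs, CDS and introns
partition the transcript span exactly, which is enforced by tests.
`derive_shores` builds the conventional ±2-kb island flanks with island
sequence subtracted. `annotate_dmrs` reports every overlap of ≥ 1 bp,
ignoring strand, with no feature precedence by default (a DMR spanning an
exon/intron boundary counts in both classes); a `precedence` argument
yields disjoint counts for users who need tallies that sum to the number of
DMRs. DMRs hitting nothing are tallied as intergenic.

## The synthetic generator

`simulate_methylome` generates the structure the caller assumes, with known
truth, so every stage is testable without external data:

* **Positions**: adjacent gaps drawn as $\mathrm{round}(2^x)$ (floored at
  2 bp) with $x$ from the mixture $\lambda_1 = 0.85$, $\mu_1 = 4.65$,
  $\sigma_1 = 1.2$, $\mu_2 = 9.5$, $\sigma_2 = 1.5$. These defaults put the
  weighted-density crossing at $x^\* = 7.51$ (182 bp), the neighbourhood
  reported for real ERRBS comparisons; the generator exposes the exact
  crossing (`mixture_crossing`) as ground truth for cutoff recovery. A
  configurable fraction (default 10%) of CpGs is duplicated 1 bp downstream
  on the minus strand to emulate un-destranded input.
* **Planted DMRs**: position clusters (segmented at the true crossing
  distance) holding ≥ 10 CpGs are sampled (50 by default) and planted whole,
  with random direction and mean difference ±40 percentage points
  (SD 5) — an effect size typical of strong differential regions between
  disease and control tissue.
* **p-values**: a latent AR(1) z-process (coefficient 0.3 by default) over
  100-bp bins contributes half of each site's probit-scale variance
  (`bin_weight = 0.5`), giving null p-values that are marginally uniform but
  spatially autocorrelated — the situation the Stouffer–Liptak adjustment
  exists for. Planted CpGs get the same latent z shifted by 5, so effect
  size and significance are coherent (roughly what a per-site exact test
  yields at deep pooled coverage for a 40-point difference). q-values are BH
  over all sites. The bin-mean autocorrelation has the closed form
  $w\rho^\ell / (w + (1-w)/m)$ (`analytic_bin_acf`), used to calibrate the
  ACF estimator.

What the generator does **not** emulate: read-level sampling noise tied to
coverage (coverage is drawn but decorative), bisulfite conversion error,
coverage dropout inside clusters, unbalanced hyper/hypo landscapes, or
chromosome-scale covariates. Passing the recovery gates therefore shows the
pipeline is correct and calibrated *under its own model assumptions*; it is
not evidence about any particular tissue contrast.

## Numerical choices and degenerate inputs

* EM starts from a median split of the sample (deterministic; no
  seed-dependent label flips), stops on a relative log-likelihood change
  below $10^{-8}$, and errors on collapsed components
  ($\sigma < 10^{-6}$ or $\lambda < 10^{-4}$) or constant samples rather
  than returning nonsense. Fewer than 500 retained gaps is an error.
* A cost minimum at the search-interval boundary (components that do not
  separate) returns with a warning rather than failing.
* Undefined ACF lags (constant series or < 3 pairs) become 0 with a
  warning: distant pairs are then treated as independent, the conservative
  reading for sparse data.
* Duplicate (chromosome, position, strand) records are a hard error;
  destranding is deliberately left upstream, and same-position
  opposite-strand records are legal input.
* TSV output serialises doubles at 17 significant digits, so written DMR
  tables round-trip bit-exactly.

## Problem sizes used in validation

The bundled tests validate parameter recovery on 20,000-draw mixtures,
segmentation against a pairwise oracle on 1,000 random inputs, null
calibration of the combined p-value on 10,000 simulated regions, ACF
calibration on ~6,000 occupied bins, and end-to-end recovery on the default
200,000-CpG synthetic methylome (50 planted DMRs), where the pipeline is
expected to recover ≥ 90% of planted regions at q < 0.05 with base-level
Jaccard ≥ 0.8 and ≤ 10% of calls outside truth. These sizes give sampling
error comfortably below each asserted tolerance while keeping the whole
suite fast.

## Known limitations

* Exactly two mixture components; data whose gap distribution is unimodal
  or has heavier structure should use a user-fixed cutoff
  (`dist_cutoff = <bp>`).
* The lag mapping $\lceil d/\text{bin} \rceil$ treats all pairs in the same
  bin-distance class identically; sub-bin correlation structure is not
  modelled.
* Nearby post-filter regions are never merged, and there is no
  sliding-window alternative.
* Annotation treats each transcript independently; no collapsing to
  canonical transcripts.
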
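# dmrseg

Empirical detection, significance testing and annotation of differentially
methylated regions (DMRs) from per-CpG differential-methylation tables, for
enrichment-based bisulfite sequencing data (RRBS, ERRBS and similar).

Per-site callers (methylKit-style pipelines) report a p-value, q-value and
methylation difference for every covered cytosine. `dmrseg` aggregates those
sites into regions. Its users are epigenomics analysts who already have
per-CpG differential calls and want region-level calls whose boundary
distance is derived from the data rather than fixed a priori.

## The method

Enrichment protocols cover CpGs in clusters, so the log2 distances between
adjacent covered CpGs are bimodal: a *regional* (within-cluster) component
and a *boundary* (between-cluster) component. After removing the 1-bp
opposite-strand spike, `dmrseg` fits the two-component normal mixture

&nbsp;&nbsp;&nbsp;&nbsp;F(x) = λ₁·N(μ₁, σ₁²) + λ₂·N(μ₂, σ₂²),&nbsp;&nbsp; λ₁ + λ₂ = 1,&nbsp;&nbsp; μ₁ < μ₂

by EM, and places the region-boundary cutoff at the minimiser of the
mixing-weighted misclassification cost

&nbsp;&nbsp;&nbsp;&nbsp;C(x) = λ₁·P₁(X ≥ x) + λ₂·P₂(X ≤ x),&nbsp;&nbsp;&nbsp; x̂ = argminₓ C(x),&nbsp;&nbsp;&nbsp; D = round(2^x̂).

CpGs are segmented into regions wherever an adjacent gap exceeds D, and
candidate regions must pass three filters: ≥ 1 DMC, ≥ 3 CpGs, and absolute
mean methylation difference > 20 percentage points (difference convention:
treatment − control). Each surviving region gets a dependence-adjusted
Stouffer–Liptak combined p-value,

&nbsp;&nbsp;&nbsp;&nbsp;T = Σᵢ zᵢ / √(Σᵢⱼ σᵢⱼ),&nbsp;&nbsp; zᵢ = Φ⁻¹(1 − pᵢ),

where σ is a member-pair correlation matrix read off a binned (default
100 bp) spatial autocorrelation estimate of the probit-transformed
p-values, followed by Benjamini–Hochberg FDR correction. Annotation maps
DMRs onto promoters, UTRs, CDS, introns, CpG islands and ±2-kb shores, and
arbitrary BED tracks.

A seeded synthetic-methylome generator (`simulate_methylome`) with known
ground truth — mixture-distributed gaps, planted DMRs, AR(1)-autocorrelated
p-values — backs the test suite and the acceptance script.

## Worked example

```r
library(dmrseg)

# a 40,000-CpG synthetic methylome with 12 planted DMRs
sim <- simulate_methylome(synth_config(seed = 1, n_cpgs = 40000L, n_dmrs = 12L))

res <- call_dmrs(sim$cpgs)   # or: read_dmc_table("diff.tsv") for real data
res
#> Empirical DMR call
#>   distance cutoff: 183 bp (fitted)
#>   regions segmented: 5779; DMRs after filters: 12
#>   hyper: 5, hypo: 7; 12 at q < 0.05

res$fit
#> Two-component normal mixture fit
#>   component 1 (regional): lambda = 0.8491, mu = 4.6360, sigma = 1.2105
#>   component 2 (boundary): lambda = 0.1509, mu = 9.5168, sigma = 1.5063
#>   loglik = -80293.797 after 81 iterations (converged: TRUE)

dmrs <- res$dmrs[res$dmrs$q_value < 0.05, ]
head(dmrs[, c("chrom", "start", "end", "cpg_count", "dmc_count",
              "mean_diff", "direction", "q_value")], 3)
#>   chrom   start     end cpg_count dmc_count mean_diff direction      q_value
#> 1  chr1  456367  456699        13         8 -40.91526      hypo 4.413679e-19
#> 2  chr2  768406  769336        24        20 -40.52131      hypo 1.541353e-32
#> 3  chr2 2139789 2140544        23        19  40.61966     hyper 1.810330e-29

summarize_dmrs(dmrs)
#> DMRs: 12 (5 hypermethylated, 7 hypomethylated)
#> length (bp):       226  313  370  487  931
#> mean diff (pp):    -43.14  -40.62  -38.84   39.96   40.91
#> DMCs per DMR:       6.00   8.00   9.00  14.25  20.00

evaluate_recovery(dmrs, sim$truth$dmrs)
#> sensitivity 1.00, jaccard 1.00, false-call rate 0.00
```

The fitted cutoff (183 bp here) is the data's own estimate of the distance
separating within-cluster from between-cluster CpG gaps; the mixture
parameters match the generating values (λ₁ = 0.85, μ₁ = 4.65, μ₂ = 9.5);
and every planted region is recovered at q < 0.05 with exact boundaries
(base-level Jaccard 1.00) and no spurious calls.

Annotation on real data:

```r
genes   <- read_gene_model("refGene.refflat")
islands <- read_interval_track("cpg_islands.bed", "cpg_island")
tracks  <- c(derive_gene_parts(genes),
             list(cpg_island = islands, shore = derive_shores(islands)))
ann <- annotate_dmrs(dmrs, tracks)
ann$counts   # distinct DMRs per feature class, plus "intergenic"
```

A command-line front end with `call`, `simulate`, `annotate` and `summary`
subcommands is installed at `inst/scripts/dmrseg.R`
(`Rscript dmrseg.R call --input diff.tsv --out outdir --dist-cutoff auto`).

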
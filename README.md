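# resort

Region-based cell sorting for spatial transcriptomics (ST) deconvolution.

Sequencing-based ST platforms (e.g. 10x Visium) measure gene expression at
spatial spots that each capture roughly ten cells, so every spot is a small
mixture of cell types. Reference-based deconvolution estimates the mixture
proportions from a single-cell reference — but references from other
experiments carry batch and platform effects that distort the estimates.
`resort` implements a region-based strategy that sidesteps the external
reference at the coarse level: it extracts molecularly homogeneous spatial
regions from the ST sample itself, uses the region spots as a
*pseudo-internal reference*, deconvolves region-level cell-type
proportions against it, and only consults an external reference for finer
cell types that never form a spatial region of their own.

The package is aimed at method developers and analysts who want a fully
scriptable, offline version of this workflow, together with a simulator
that produces ST samples with known ground-truth composition for
benchmarking.

## The model in brief

**Simulator.** On an `n_r x n_c` grid, disjoint geometric regions carry
one region-level cell type each. For a spot `s` outside every region, the
affinity to region `r` is inverse distance plus noise,

    A[s,r] = 1 / min_{s' in r} Dist(s, s') + delta_r,   delta_r ~ N(0, sd)

normalized to proportions `P~[s,r] = A[s,r] / sum_r' A[s,r']`; in-region
spots are pure. Proportions become cell counts `C[s,r] =
floor(10 * P~[s,r])` and the saved ground truth is the renormalized count.
For each spot, `C[s,r]` cells of type `r` are drawn without replacement
from a single-cell reference and 10% of their reads are retained
(binomial thinning), matching the library scale of real spots. Immune
infiltration is emulated by replacing cells in 10% of the pure tumor
spots with immune cells at a proportion drawn from a truncated
Normal(0.5, 0.2).

**Region extraction.** Counts are library-normalized and log-transformed,
embedded with PCA, and a graph is built whose edges connect spatially
adjacent spots weighted by the Pearson correlation of their embeddings.
Edges below an automatically selected threshold epsilon are dropped;
connected components with at least `m = 40` spots become regions,
everything else stays unassigned.

**Deconvolution.** The pseudo-internal reference Omega holds the region
spots' expression labeled with region-level types. Per-type signatures
(mean library-normalized profiles over marker genes, optionally split
into k-means sub-profiles) drive a per-spot solver — non-negative least
squares, or a multinomial maximum-likelihood fit — whose coefficients are
renormalized to sum to one. Finer types use the two-step product
estimator: with `Y~_T` the spot's region-level proportion of type `T` and
`Y~_t` the within-`T` proportion of subtype `t` estimated from an
external reference `omega`,

    Y_t = Y~_T * Y~_t

so fine-level proportions inherit the region-level structure and still
sum to one.

**Evaluation.** Per-spot Pearson correlation and Kullback–Leibler
divergence against ground truth, infiltrated-vs-pure tumor spot
classification with class-size-weighted F1, and stratification of spots
into pure/mixture microenvironment categories.

## Worked example

```r
library(resort)

## 1. A synthetic study: three tissue compartments on a 30 x 30 grid
sc  <- scenario("three-region", n_rows = 30, n_cols = 30, seed = 1)
sim <- simulate_st(sc$reference, sc$layout, sc$config)
sim$spatial
#> spatial_counts: 900 spots x 1000 genes (grid 30 x 30)

## 2. Extract molecularly homogeneous spatial regions
asn <- detect_regions(sim$spatial, sc$config)
asn
#> region_assignment: 4 regions (R1: 158, R2: 156, R3: 74, R4: 70),
#>   442 unassigned of 900 spots (epsilon = 0.614, m = 40)

## 3. Pseudo-internal reference from the region spots
map <- map_regions_by_truth(asn, sim$truth_region)  # analyst-supplied on real data
omega <- build_pseudo_reference(sim$spatial, asn, map)
omega
#> pseudo_reference: 458 spots x 1000 genes (cancer: 156, ductal: 144, normal: 158)

## 4. Region-level deconvolution
sig <- region_profiles(omega, k_sub = 2)
est <- deconvolve_regions(sim$spatial, sig, method = "mle")
round(unclass(est)[c("s000_008", "s015_015"), ], 3)
#>          cancer ductal normal
#> s000_008  0.683  0.018  0.299
#> s015_015  0.404  0.343  0.254

## 5. Score against the simulation ground truth
metrics <- spot_metrics(sim$truth_region, est)
str(attr(metrics, "summary"))
#> List of 5
#>  $ mean_pearson       : num 0.97
#>  $ median_pearson     : num 0.998
#>  $ mean_kl            : num 0.0593
#>  $ median_kl          : num 0.0385
#>  $ n_undefined_pearson: int 4
```

The four detected regions map onto the three generating compartments
(the split ductal region is re-merged by the type map); spot
`s000_008` sits between the cancer and normal circles and is recovered
as a cancer/normal mixture, and the summary shows near-perfect per-spot
correlation with a mean divergence of about 0.06 nats against the known
composition. The `#>` lines are the output the code prints.

A command-line interface wrapping the same functions ships in
`inst/cli/resort.R`, with subcommands `fixtures`, `simulate`, `regions`,
`build-ref`, `deconvolve` and `evaluate` (see `Rscript inst/cli/resort.R`
for usage).

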
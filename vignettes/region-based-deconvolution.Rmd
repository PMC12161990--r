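---
title: "Region-based deconvolution of spatial transcriptomics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based deconvolution of spatial transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(resort)
```

This vignette explains the statistical machinery behind `resort`: the
generative model of its simulator, the region-extraction and
deconvolution procedures, the tunable parameters, and the places where
the design was genuinely open and a choice had to be made. It states no
empirical result beyond what the package's own test suite and acceptance
script compute.

## Why a pseudo-internal reference

Reference-based deconvolution decomposes each ST spot's expression
profile into cell-type signatures learned from a single-cell reference.
When that reference comes from another experiment, per-gene batch and
platform effects bias the signatures and hence the estimated
proportions. The key observation exploited here is that sequencing-based
ST samples with thousands of spots usually contain *regions* — spatially
contiguous runs of spots dominated by one coarse cell type (tumor,
ductal, stroma, ...). Spots inside such regions are nearly pure
observations of their type *on the same platform as the sample itself*,
so they can serve as an internal reference for region-level
deconvolution. Only cell types that never form a region (immune
subtypes, fine secondary types) still need an external reference, and
even these benefit from being constrained by the region-level estimates.

## The simulator

The simulator produces ST samples with known composition, so every
downstream claim can be scored against ground truth.

**Layout.** Disjoint geometric shapes (circles, rectangles) on a
rectangular grid carry one region-level type each. Coordinates are
0-based integers and distances are Euclidean on these raw integers; the
grid has no physical units.

**Mixing proportions.** A spot inside a region is pure: regions model
homogeneous cell populations, and an inverse-distance affinity would be
undefined at distance zero anyway. For an out-of-region spot `s`, the
affinity to region `r` is `1 / d(s, r) + delta`, where `d(s, r)` is the
distance to the nearest spot of `r` and `delta ~ N(0, noise_sd)` is
independent per spot-region pair. Affinities are clipped below at `1e-6`
to stay positive (the noise can otherwise push a distant spot's affinity
negative) and normalized to sum to one. `noise_sd` defaults to 0.05 — a
mild perturbation that breaks exact symmetry without overwhelming the
distance structure.

**From proportions to cells.** Each spot holds `cells_per_spot = 10`
cells, the Visium capture scale. Counts are the *floor* of
`10 * proportion`: truncation (rather than rounding) guarantees the
counts never exceed the capture size. The floored counts are renormalized
and saved as the evaluation ground truth, so truth proportions are
multiples of one cell. A spot whose row floors to all zeros (possible
only with many types) receives one cell of its largest-proportion type,
with ties to the lowest type index — otherwise the renormalization would
divide by zero.

**Reads.** For each spot, the required number of cells per type is drawn
without replacement from the single-cell reference, and each read of the
drawn cells is retained independently with probability
`downsample_rate = 0.10`, which brings per-spot libraries to the order
of magnitude of real spots. Retention is implemented as one
`Binomial(total reads, rate)` draw per gene on the summed counts —
distributionally identical to thinning each cell separately, because
independent binomials with a common rate add. Exact subsampling of a
fixed fraction of reads would be the alternative reading; binomial
thinning was chosen and is flagged in the configuration as
`downsample_mode`.

**Fine-level truth.** Cells are drawn per region-level type; the fine
labels of the cells actually drawn define the fine-level ground truth,
so both levels are emitted consistently from one draw.

**Infiltration.** To emulate immune infiltration, a fraction (default
10%) of the *pure tumor* spots is selected uniformly; each receives an
immune proportion `q` drawn from `Normal(0.5, 0.2)` truncated to (0, 1)
by rejection (the untruncated draw leaves the interval with probability
about 1.2%, and no handling of out-of-range draws is canonical — with
these parameters the truncation leaves the mean at 0.5 exactly, by
symmetry, and shrinks the standard deviation to about 0.191). The spot
then has `max(1, floor(10 q))` of its cells *replaced* by immune cells,
keeping the capture size fixed; adding cells on top would be the other
defensible reading, but substitution preserves the per-spot cell-count
contract.

## Region extraction

Counts are normalized per spot to the median library size and
log-transformed (`log1p`), embedded by PCA (`k_pcs = 10` components,
column-centered, with the deterministic sign convention that each
component's largest-magnitude loading is positive), and turned into a
graph: one node per spot, one edge per spatially adjacent pair, weighted
by the Pearson correlation of the two embeddings. Adjacency defaults to
the 4-neighborhood (`grid4`); 8-neighborhood and an odd-row-offset
hexagonal scheme (the Visium arrangement) are available, since nothing
in the procedure fixes the connectivity.

Edges below a threshold epsilon are dropped and connected components
with at least `m = 40` spots (the common Visium default) become regions;
the threshold "more than m" is implemented inclusively as `>= m`, an
off-by-one that is immaterial at the default. Region ids are ordered by
decreasing size, ties broken by the smallest member position, so runs
are reproducible.

**Choosing epsilon.** The selection rule scans the 50th–99th percentiles
of the edge weights. For each candidate it computes the *region count*
(components of size at least `m`) and the *coverage* (fraction of spots
inside such components). Candidates achieving the maximal region count
are preferred, and among them the largest epsilon whose coverage is
within 0.05 of their maximum is returned. The region-count preference is
deliberate: at too low a threshold, distinct regions merge through
boundary mixture spots, and a merged region poisons the pseudo-internal
reference with mislabeled spots, whereas an over-split region is
harmless — the analyst's region-to-type mapping simply assigns both
fragments the same type. A manual `epsilon` override is available in the
configuration.

## Deconvolution

**The pseudo-internal reference.** Omega collects the expression rows of
all spots inside labeled regions, each carrying the region-level type its
region maps to; unassigned spots — the likely mixtures — are excluded.
The mapping from region ids to types is the analyst's on real data and
can be derived from the generating truth in simulations
(`map_regions_by_truth()`).

**Signatures.** Per type, the signature is the mean of the
library-normalized profiles. Genes are restricted to the union of each
type's top 200 one-vs-rest log-fold-change genes; with
`k_sub > 1`, each type is additionally split into k-means sub-profiles
(deterministic farthest-point seeding) that the solver fits separately
and sums back into the parent type. Sub-profiles matter when a region
type hosts several fine types in varying ratios: a single mean signature
misattributes that within-type variation to other types, while a small
dictionary per type absorbs it.

**Solvers.** Two per-spot backends share the interface:

* `nnls` — non-negative least squares of the library-normalized profile
  against the signatures, coefficients renormalized to sum to one. It is
  exact on noiseless mixtures and is the default.
* `mle` — the spot's counts over the signature genes are modeled as
  `Multinomial(L, sum_k p_k S_k)` and fitted by EM to convergence
  (tolerance `1e-9`, at most 1000 iterations). The likelihood weighting
  is better matched to sparse counts than least squares on frequencies.
  After convergence the estimate is shrunk toward the uniform
  composition by `prior_cells = 0.5` cell equivalents: with ten cells
  per spot, proportions below one cell are not identifiable, and the
  maximum-likelihood boundary zeros would otherwise claim certainty the
  data cannot support. The shrinkage keeps every component strictly
  positive at about half a cell's worth of mass — consequential when
  estimates are scored by divergence measures, which are unbounded at
  zero.

Degenerate spots (all-zero solution or empty library) fall back to
uniform proportions with a warning. Types that form no region (e.g.
infiltrating immune cells) are appended to the signature matrix from an
external reference via `augment_signatures()`, which also extends the
fitted gene set with the appended type's own markers — without that
extension the appended type would be fitted blind to the genes that
identify it, since the pseudo-internal gene selection cannot rank genes
for a type it never saw.

**Finer types.** The two-step estimator multiplies the spot's
region-level proportion of type `T` by its within-`T` subtype
proportions estimated against fine-type signatures from the external
reference, renormalized within each block. Because both factors are
row-normalized, full fine-level rows sum to one identically; the block
renormalization is what makes the product estimator respect the simplex,
and single-subtype blocks reduce to the region-level estimate itself.

## Evaluation

Per-spot Pearson correlation treats each spot's proportion vectors as
paired observations; spots with a constant (e.g. uniform) truth vector
have undefined correlation and are reported as missing rather than
zero. The KL divergence is computed as `KL(truth || estimate)` — the
direction penalizes estimates that miss types the truth supports — after
adding a pseudo-count of `1e-9` to both rows and renormalizing, which
keeps the score finite. Infiltration calls threshold the estimated
immune proportion at 5% within the tumor-region spots, reporting
per-class precision/recall/F1 and the class-size-weighted F1 appropriate
for the imbalanced problem. Stratification labels spots pure when the
top proportion reaches 0.9 and as a two-type mixture when the top two
types both reach 0.1; a mixture category can then be split into
infiltrated versus peripheral spots by a region boundary. The 0.9/0.1
defaults are package choices — no canonical rule exists for these
categories.

## The synthetic references

Fixture references draw counts from a negative binomial (baseline mean
0.5 per gene, size 0.5), giving sparse overdispersed profiles, with each
fine type's disjoint marker block up-scaled eight-fold in expectation.
Defaults are a 1000-gene panel, 25 markers per fine type and 60 cells
per fine type: the panel scale and the resulting per-spot libraries
(hundreds of reads) sit at the low end of real spot libraries, and the
marker mass (about a sixth of a cell's reads on its own markers) models
well-separated tissue compartments, the regime in which region-level
types are distinguishable at ten cells per spot. The external-reference
generator redraws cells from the same type model and multiplies every
gene's mean by a log-normal factor (`sigma = 0.5`) shared across cells —
the simplest mechanism that preserves type structure while injecting
systematic gene-level platform effects.

What the fixtures deliberately do not model: hexagonal spot geometry and
spot diameter, capture-efficiency gene bias, spatial expression
gradients within a region, doublet-style artifacts, or any
distributional fidelity to a particular tissue. Tests passing on these
fixtures therefore demonstrate the pipeline's correctness and its
robustness to batch-shifted references under idealized, well-separated
compartments — not performance on any specific real dataset.

## Problem sizes and determinism

The test suite exercises the full pipeline on 30 x 30 grids (900 spots,
1000 genes) and the simulator contract on the standard 50 x 50 grid
(2500 spots); these sizes keep a full run in tens of seconds while
leaving every pipeline stage nontrivial. All randomness flows through
explicit seeds: `simulate_st()` seeds from its configuration, fixture
generators use the caller's RNG state, and scenario bundles fix one seed
for reference and configuration together, so identical inputs reproduce
identical outputs bitwise.

## Known limitations

* The approach presumes that coarse cell types form spatial regions; in
  tissues where major types are spatially interleaved (e.g. neurons and
  glia), few spots are pure and the pseudo-internal reference loses its
  advantage.
* Cell types absent from both the regions and the external reference are
  invisible — an intrinsic limit of reference-based deconvolution.
* The epsilon selection rule is a pragmatic heuristic; pathological
  weight distributions (e.g. near-constant weights) fall back to simple
  defaults with warnings rather than failing.
* Region-level estimates feed the fine-level product estimator as hard
  constraints: a missed region type propagates zeros to all its
  subtypes.
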
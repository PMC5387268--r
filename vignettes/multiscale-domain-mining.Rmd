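---
title: "Multi-scale structural domain mining with spectral graph wavelets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale structural domain mining with spectral graph wavelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicwavelets)
```

## Model and assumptions

A binned intra-chromosomal Hi-C matrix is symmetric and non-negative, so it
can be read as the weighted adjacency matrix `W` of a network whose nodes
are the genomic loci (fixed-size bins, typically 100 kb) and whose edge
weights are co-localisation counts. Structural domains — TADs and their
larger assemblies — appear as communities of this network: groups of loci
more densely connected among themselves than with the rest of the
chromosome. Working on the graph rather than along the genome axis has two
consequences we exploit: no scale of observation is privileged, and no
assumption is made that a domain is a contiguous genomic interval (the
contiguity of each community is *measured*, see `P_int` below). The method
only assumes the matrix is a meaningful similarity — it performs no
normalisation (ICE or otherwise), which is deliberately out of scope and
should be done upstream if desired.

### Locus filtering and masked coordinates

Bins with aberrant coverage create spurious communities.
`filter_loci(M, low_q, high_q)` removes bins whose marginal contact sum is
zero, below the `low_q` quantile, or above the `high_q` quantile of the
nonzero marginals (defaults `0.005`/`0.995`, linear-interpolation type-7
quantiles — frozen so filtering is reproducible). Surviving bins are
concatenated into *masked positions*; the `MaskedIndexMap` makes the
mapping invertible. Everything downstream runs in masked coordinates;
`unmask()` projects results back and reports the *inflation* (genomic
length over masked length), which flags communities artificially bridging a
masked gap such as a centromere.

### Wavelets, scales and the correlation distance

With `L = Deg − W` the combinatorial Laplacian (eigenvalues
`0 = lambda_1 < lambda_2 <= ... <= lambda_max` on a connected component),
the wavelet centred on node `a` at scale `s` is `g(sL) delta_a`. The kernel
`g` is the standard spectral-graph-wavelet band-pass design: `x^2` below
the pass-band `[1, 2]`, `4/x^2` above it, and the unique cubic
(`-5 + 11x - 6x^2 + x^3`) joining the two branches smoothly. The
combinatorial (rather than normalised) Laplacian is the default and the
kernel is configurable; both choices are stated here because results do
depend on them.

The scale grid ties the kernel to the spectrum of *each connected
component*: at `s_max` the kernel peak (at `x* = 2 − 1/sqrt(3) ≈ 1.42`)
sits on `lambda_2`, so the wavelet responds to the slowest structural mode
(whole-component scale); at `s_min` it sits on `lambda_max`, the most
localised mode. `J` scales (default 100) are geometrically spaced in
between. Doubling all edge weights doubles the spectrum and halves every
scale — the grid is invariant to the overall count level in this sense.

At a scale `s`, the similarity of two loci is the Pearson correlation of
their wavelets, `C(s)(a,b)`, and `D(s) = 1 − C(s)` is the correlation
distance fed to clustering. Pairs in different components get the maximal
distance `D = 2`. A node whose wavelet has zero variance (degenerate
features) is flagged and assigned `C = 0` to every other node.

### Fast estimator

Computing all `n` wavelets exactly requires `n` transforms (equivalently a
dense eigendecomposition) — `exact_correlation_distance()` does exactly
this and serves as the oracle in the test suite. The production path,
`fast_correlation_distance()`, filters `eta` standard-Gaussian random
vectors through `g(sL)` and correlates the resulting `eta`-dimensional
feature rows; as `eta` grows this converges to the exact correlation
(entrywise sampling error ~ `1/sqrt(eta)`). The default `eta = 200` is the
operating point used throughout. The filter is applied as an order-50
Chebyshev polynomial in `L` over `[0, lambda_max]`; coefficients are
computed with a high-resolution quadrature (≥ 1000 points) so they are the
true truncated-series coefficients rather than an aliased collocation fit.
`lambda_max` comes from a dense eigendecomposition for components up to
4096 nodes, otherwise from a power iteration inflated by 1% so it remains
an upper bound; `lambda_2` likewise (deflated power iteration on the
spectral complement).

One caveat stated plainly: when `s` approaches `s_max` on a component with
a very small `lambda_2`, the kernel support `[1/s, 2/s]` becomes a spike
near the bottom of `[0, lambda_max]` that an order-50 polynomial cannot
resolve sharply. The estimator remains usable (the fitted polynomial still
weights the low spectrum most) but its entrywise agreement with the exact
transform degrades there; `fast_correlation_distance()` warns when `s` is
far outside the component's scale range. The convergence test in the suite
is therefore run at an intermediate scale, where order 50 keeps the
operator error well below the sampling error floor.

### Cutting the dendrogram

Average-linkage clustering of `D(s)` gives a merge-height ladder
`h_1 <= ... <= h_{n-1}`. The partition is obtained by cutting at the widest
gap among the following candidates, ties going to fewer communities:

* below the first merge (gap `h_1 − 0`) — yields all singletons;
* between consecutive merges `j` and `j+1` — yields `n − j` communities;
* above the final merge, with the gap measured up to `D = 1`, the
  uncorrelated reference level (`C = 0`) — yields one community.

If every merge occurs at the same height the distance carries no
structure and the component is returned as a single community. This rule is
a frozen, reproducible approximation of the "most relevant partition"
criterion of the multi-scale community-mining literature, which is
stability-based and not fully specified by its published description; the
cut criterion is isolated behind `partition_at_scale()` so alternatives can
be plugged in. All-singleton and single-community partitions are retained
in the output: regimes of scales with only trivial partitions are a
finding (they signal absence of structure at those scales), not an
artefact.

### Interval-communities, borders, hierarchy

For each non-trivial community (size ≥ 2), `P_int` is the length of its
largest run of consecutive masked bins divided by its size: 1 for a perfect
interval, `1/N` when no two bins are consecutive. Communities with
`P_int >= 0.95` are reduced to their main interval. Identical masked
intervals found at several scales are kept once, with the scale set
recorded; intervals that more than double in genomic size when unmasked
(`inflation > 2`) are dropped. Both thresholds are the method's operating
point and are exposed as arguments.

At each scale, a border exists wherever two interval-communities touch, and
carries the minimum of the two flanking lengths; the final border database
takes, per distinct position, the maximum of these per-scale lengths, so a
border's associated length reflects the largest structure it delimits.
Cross-scale conservation — for each pair `s1 < s2`, the fraction of `s2`
borders that exist (exact pixel match by default, ±1 pixel behind a flag)
among `s1` borders — quantifies how nested the hierarchy is; a matrix of
values near 1 means larger structures arise by merging smaller ones without
new borders appearing.

Interval-community length distributions are summarised by a histogram and,
when at least 20 lengths and 3 occupied bins are available, by the
ordinary-least-squares slope of `log10(count)` against `log10(length)` with
zero bins dropped (a descriptive straight-line-in-log-log summary;
maximum-likelihood tail fitting is deliberately not used). The histogram
bin width matters for this estimator: bins so fine that expected counts
fall below ~1 in the fit range bias the zero-truncated regression upward.
The parameter-recovery tests use 1 Mb bins on lengths drawn from a
`l^-1.3` density over 2–100 Mb, where the estimator is unbiased; with
100 kb bins at the same sample size (5000) the bias reaches ~+0.2.

### Comparing domain sets and the insulation ratio

Domain sets of different origins (interval-communities, external TAD
calls) are not partitions, so partition-similarity indices do not apply.
The comparisons implemented are: mutual coverage
`m_c = |d1 ∩ d2| / max(L1, L2)`; per-domain best mutual coverage against a
reference set; mean-coverage and match-proportion curves over groups of 50
domains sorted by length (a match is `bm_c >= 0.8`); and border matching
within an inclusive 100 kb tolerance over groups of 100 borders sorted by
associated length. For border comparisons a reference subset is first
selected greedily by decreasing associated length until its ±1-pixel
footprint covers 35% of the genome — making 35% the chance-level match
rate, which the test suite verifies by simulation.

The insulation diagnostic compares, at each separation `d`, contacts
between loci straddling a community *centre* with contacts straddling a
community *border*. Counts are pooled over all communities of a length
category (seven classes from 0.3 to 100 Mb) and each side is normalised by
its number of contributing pairs before the ratio is taken, so a uniform
matrix gives exactly 1 at every distance; pairs falling outside the matrix
are skipped, not zero-filled. When `d` has the wrong parity for a
symmetric pair the split is asymmetric by half a bin, floor on the left
side — an arbitrary but frozen convention.

## The synthetic validation surface

Real Hi-C matrices from public repositories are deliberately not required;
the `synthetic` generators produce the statistical structure the method
assumes, so the whole pipeline is testable offline.

* `generate_block_benchmark()` — the reference benchmark: 2000 loci tiled by
  40 pairs of 20- and 30-locus blocks with internal interaction 60, first
  and second sub/super-diagonals overwritten to 80 and 70 (these, not the
  noise, keep the chain of blocks connected), and additive Poisson noise of
  mean `lambda = 50` on every interacting (structurally nonzero) pair,
  mirrored. Noise is *not* added to non-interacting pairs: a dense noise
  floor would compress the Laplacian spectrum into a few-percent band and
  destroy all spectral discrimination, contradicting the construction's
  stated purpose of keeping connectivity through the sub-diagonals. With
  the defaults the pipeline (30 scales, `eta = 200`) recovers all 80
  planted domains; the noise-free `lambda = 0` variant is a stricter,
  faster smoke test.
* `generate_nested_blocks()` — hierarchical blocks for border-conservation
  tests. The two-level configuration used in the tests (2 × 50 within
  4 × 25, values 10 and 60, `lambda = 5`) steps the density by roughly an
  order of magnitude per level, mirroring the in-domain/background contrast
  of the flat benchmark, so each level dominates the dendrogram cut over
  its own range of scales; with a weaker step (e.g. 30 vs 60) the coarse
  level wins at every scale and the fine level never surfaces.
* `generate_armlike()` — a degenerate, condensed-chromosome-like fixture:
  two mega-blocks (arms) with weak inter-arm contact and a strong
  near-diagonal band, no intermediate structure. The expected mining
  output — only singletons below a critical scale, then an abrupt split
  into the two arms with no intermediate-size interval-communities — is
  what a robust method should produce when no TAD-like structure exists.
* `sample_domain_lengths()` — truncated power-law lengths for validating
  the exponent fit.

All generators are seed-deterministic, and different seeds change only the
noise layer.

What passing these tests does *not* show: real Hi-C matrices have
distance-decaying contact backgrounds, coverage heterogeneity, unmappable
regions and normalisation artefacts that the generators do not emulate.
The synthetic surface validates the machinery (transform, estimator,
clustering, reduction, statistics), not biological calling performance.

## Numerical choices and degenerate inputs

* Quantile convention for filtering: type 7, frozen.
* Chebyshev order 50, coefficients from ≥ 1000-point quadrature;
  `lambda_max` bound inflated 1% on the power-iteration path.
* Random vectors: one RNG stream per (component, scale) derived
  deterministically from the master seed, so results are independent of
  execution order and reproducible under parallelisation.
* Pearson correlations use population moments (the denominator convention
  cancels in the correlation); values are clamped to `[-1, 1]`;
  zero-variance features give `C = 0` off-diagonal.
* Dendrogram cut ties break toward fewer communities; `n = 1` components
  are singleton partitions; cutting uses `k` (not height) so occasional
  average-linkage inversions are harmless.
* Empty interval-community databases are legal output (arm-like inputs at
  small scales); conservation entries for scales without borders are
  missing values, never zeros.
* De-duplication keys on the masked interval exactly; near-identical
  intervals offset by one pixel count as distinct (a possible source of
  small count differences against other implementations, noted, with a
  ±1-pixel tolerance flag available for border conservation only).

## Problem sizes in the test suite

The suite exercises the full 2000-locus benchmark once (about 1.5 minutes:
matrix generation, spectrum bounds, 30 scales × 200 random vectors,
clustering and extraction) and otherwise uses 50–500-locus fixtures chosen
so each oracle comparison (dense eigendecomposition, brute-force grouping,
exhaustive maxima) runs in seconds. The estimator-convergence check uses
`eta = 20000` on 50 nodes at an intermediate scale, where the Chebyshev
operator error is below the sampling floor.

## Known limitations

* At top-of-range scales on near-block-diagonal matrices (tiny
  `lambda_2`), partitions merge genuinely coupled blocks into chain
  segments; whether such large-scale communities are biologically
  meaningful must be judged with the border-conservation matrix and the
  insulation ratio, not assumed.
* The dendrogram-cut rule selects one partition per scale; weaker
  secondary structure at a scale is only visible at neighbouring scales.
* The power-law exponent is a descriptive OLS summary, sensitive to the
  histogram bin width as described above.
* No matrix normalisation and no trans (inter-chromosomal) mining.
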
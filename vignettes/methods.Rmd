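---
title: "Clustering binding point patterns: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering binding point patterns: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`lgcpclust` groups proteins by the spatial pattern of their binding events
inside one chromatin state. The modeling chain is:

1. **Events.** Each ChIP-seq peak is reduced to its center,
   `floor((start + end)/2)` — a single, strandless binding event. Peak
   width and summit information are deliberately discarded: the clustering
   signal is *where* a protein binds, not how broad its peaks are.
2. **Common interval.** All genome windows of one domain-level state are
   concatenated — natural chromosome order (`chr1 < chr2 < ... < chr10 <
   ... < chrX`), then start — and the concatenated axis is rescaled to
   `[0, L]` with `L = 50`. Individual state windows are too sparse to
   cluster on their own; concatenation pools a state's signal genome-wide
   while normalizing away the very different total sizes of different
   states. `L` is a pure scale choice (it trades off against the intensity
   units and the grid width) and is configurable.
3. **Point process.** Protein *i*'s mapped events are an inhomogeneous
   Poisson process with intensity `lambda_i(s)`, `s in [0, L]`.
4. **Clustering prior.** `log lambda_i` is drawn from a random
   distribution with a Dirichlet process prior, `DP(m, G0)`; proteins whose
   log-intensities coincide (the atoms of the DP draw) form a cluster and
   share one intensity function. `m` controls the expected number of
   clusters; `G0` is a mean-zero Gaussian field.

## Discretization

The Gaussian field is represented on a regular grid of `B` bins (default
`B = 100` over `[0, 50]`, i.e. two bins per unit — enough to resolve the
smooth, bump-like intensities this method targets while keeping every
Newton solve instantaneous). The continuous likelihood is replaced by
independent Poisson bin counts,

    counts_b ~ Poisson( exposure_b * exp(mean0 + z_b) ),

with `exposure_b = r * delta` when `r` processes are pooled
(`delta = L/B`). This is the standard grid approximation behind
INLA-style LGCP inference: the count model is exact for a piecewise-
constant intensity, which is how the "spline basis" is realized here
(order-1). Higher-order bases would smooth the likelihood itself and
break the exact per-bin count interpretation, so they were not made the
default.

Two deliberate likelihood choices:

* **No `log(counts!)` term.** The gridded likelihood is the discrete form
  of `prod_j lambda(s_j) * exp(-integral lambda)`, whose events are
  distinguishable points. The Poisson factorial normalizer differs between
  a pooled cluster and its members taken separately, so including it would
  systematically bias every merge/split comparison the sampler makes (in
  early testing it reversed the sign of same-intensity merge scores).
* **Constant factors dropped.** Any factor constant across partitions —
  including a constant `exp(|D|)`-type factor in the likelihood — cancels
  from all reassignment probabilities and is omitted.

## Prior on the latent field

`z` carries a second-order random-walk (RW2) precision
`Q = kappa * D2' D2 + ridge * I`:

* `kappa` (default **1.0**) — smoothness. RW2 is the canonical sparse
  discrete analogue of a smooth GP; its null space (constant + linear
  trends) is deliberately cheap, and the constant direction is handled by
  `mean0`.
* `ridge` (default **1e-8**) — makes `Q` proper so log-determinants
  exist; small enough to be statistically inert.
* `mean0` — the overall log-level, set empirically by matching the total
  count: `mean0 = log(sum(counts)/sum(exposure))`, falling back to
  `log(1/L)` for empty data. This removes the one hyperparameter the
  evidence is most sensitive to without requiring hyperparameter MCMC.

The covariance kernel and its hyperparameter treatment are the one part
of the original method description that is underspecified; RW2 with fixed
`kappa` is this package's concrete choice, and `kappa` is exposed in the
configuration for sensitivity analysis.

## Laplace approximation

The posterior mode is found by Newton iterations on the sparse system
`(Q + diag(mu)) step = grad` with a step-halving safeguard; the
acceptance slack of the line search is *relative* to `|objective|`
(absolute slack stalls the iteration once objective changes drop below
rounding noise for objectives of magnitude ~1e3). Convergence is a
gradient max-norm below `1e-8` (configurable, `laplace.tol`), at most 100
iterations; non-convergence is an error carrying the last gradient norm,
never a silent result. The log marginal likelihood is the usual Laplace
expression `loglik(zhat) + logprior(zhat) + (B/2) log 2pi -
0.5 * logdet(Q + diag(mu_hat))`.

Accuracy, measured against an independent adaptive Gauss–Hermite
quadrature oracle at `B = 5`: a few hundredths of a nat for moderate
counts, up to ~0.1 nat when bins are nearly empty (skewed posterior).
Cluster evidences differ by tens to hundreds of nats in practice, so this
error is far below the decision scale of the sampler. Two regimes are
worth flagging honestly:

* **No data.** With all counts zero the posterior is dominated by the
  RW2 null directions (prior standard deviation ~1e4 under the default
  ridge); the integrand is flat over enormous ranges and neither Laplace
  nor fixed-node quadrature pins the integral tightly. The fitted mode and
  intensity are still well behaved (flat, near zero), which is what the
  sampler consumes.
* **Weak smoothing is intentional.** With `kappa = 1` and ~4 events per
  bin, the per-bin posterior tracks per-bin Poisson noise (~50%); the
  estimator is calibrated in its mean level but individual bins are not
  pinned to ±25%. Cluster assignment depends on *relative* evidence, not
  on per-bin accuracy, and pooling a cluster's members averages this noise
  down. Users wanting visually smooth curves should raise `kappa`.
  Relatedly, pooling identical patterns preserves the curve's shape but
  not its exact values: counts and exposure double while the prior does
  not, so the pooled mode leans slightly closer to the data.

# The Dirichlet-process sampler

Reassignment follows Neal's Algorithm-3 pattern with the Laplace evidence
standing in for the intractable predictive likelihood: remove protein
*i*, then

    P(join cluster c)  ∝  n_c * exp[ Λ(c ∪ i) − Λ(c) ]
    P(new cluster)     ∝  m   * exp[ Λ({i}) ]

with log-weights max-shifted before exponentiation. This variant needs no
per-cluster latent sampling, and — because the evidence of a member set is
deterministic — the whole sampler is exactly testable against brute-force
enumeration of partitions on small `N` (the acceptance suite verifies
total-variation ≤ 0.02 against the enumerated 5-partition posterior at
`N = 3`, and against closed-form Chinese-restaurant-process probabilities
at `N = 4` with the likelihood flattened).

Defaults, and why:

* `m = 1.0` — a weakly informative DP precision (expected
  `K ≈ log N`); never reported for the original analysis, so exposed as
  `dp.m`.
* `n_iter = 200` — the chain length used for the published co-binding
  matrices; evidence caching (member-set keyed) makes desk-scale runs a
  few seconds.
* `burn_in = 0` — co-binding frequencies are computed over *all* stored
  iterations, matching the "out of the total 200 iterations" convention;
  a burn-in is available as an escape hatch.
* Initialization is all-singletons (symmetric and reproducible). With
  well-separated data the chain typically coalesces within a handful of
  sweeps.

The **co-binding matrix** is the partition-averaged co-assignment
indicator — symmetric, unit diagonal, invariant to cluster relabeling.
The **consensus partition** is Dahl's least-squares rule: the stored
partition minimizing the squared deviation from the co-binding matrix,
ties broken by earliest iteration. A stored-sample argmin (rather than a
new optimization) keeps the consensus an actually-visited partition.
Soft co-membership (e.g. a protein that genuinely straddles two modules)
is expressed by intermediate co-binding probabilities, not by the hard
consensus labels.

The **K-means baseline** mirrors the comparison methodology applied to
the original analysis: estimate each protein's intensity curve
individually, then cluster the curve matrix with seeded K-means,
selecting `k in 2..min(8, N−1)` by maximum mean silhouette width. It is a
baseline, not a recommendation — it requires a point estimate per protein
and a separate model-selection step, precisely what the DP mixture
avoids.

# The synthetic generator

`make_scenario()` draws `N` processes from `K_true` closed-form intensity
archetypes (Gaussian-bump mixtures) by Lewis–Shedler thinning, assigning
processes round-robin. Defaults *are* the stated test world: three
unimodal bumps centered at 10/25/40 on `[0, 50]`, width 3, integrating to
~150 events per process — localized shapes qualitatively matching
estimated binding intensities, separated enough that recovery is
identifiable, and small enough that a full 200-iteration chain runs in
seconds. The thinning sampler is validated distributionally against an
independent inversion sampler (Kolmogorov–Smirnov) and in mean count
against the numerical integral of the intensity.

What the generator emulates: event sparsity, cluster-shared intensities,
Poisson count noise, uneven event placement. What it does **not**
emulate: peak-calling artifacts, peak width/height variation, replicate
disagreement, chromatin-state misassignment, or correlated (non-Poisson)
binding such as clustered homotypic sites. A green recovery test
therefore establishes correctness of the inference machinery on its own
modeling assumptions — not robustness to real ChIP-seq pathologies.

# Projection details

* Window concatenation order is natural chromosome order, then start. The
  original description is silent on this; any fixed order yields a valid
  (different) embedding, and a deterministic order is required for
  reproducibility. Clustering outcomes depend on the shared axis, not on
  which valid order was chosen, because all proteins use the same map.
* Bins and windows are half-open `[start, end)`; an event on a shared
  boundary belongs to the window that starts there. The last grid bin is
  closed so an event at exactly `L` is counted.
* Two peaks whose centers map to the same coordinate are separated by the
  smallest workable floating-point jitter: simple-point patterns are
  assumed by the likelihood.

# Downstream conventions

* **State enrichment** is `log2(observed share / genomic share)` with
  Laplace smoothing of one pseudo-center per state —
  `(n_s + 1)/(n_total + S)` — so empty states stay finite and shares stay
  normalized. Note the smoothed share of an empty state is `1/(n+S)`:
  for a *tiny* state this can exceed its genomic share, so near-zero
  enrichments should be read alongside `n_centers`. The exact
  normalization behind the published enrichment heatmaps is unstated;
  this is the conventional fold-enrichment choice.
* **Proximal genes**: a protein binds a gene iff a peak center falls
  within ±2 kb of the TSS, boundaries inclusive, strand ignored.
* **Expression summaries** are descriptive (n, median TPM, mean
  log2(TPM+1)); no hypothesis test is attached because none is part of
  the method.

# Configuration and CLI

All tunables live in one flat configuration (`grid.B`, `L`,
`prior.kappa`, `prior.ridge`, `laplace.tol`, `laplace.max_iter`, `dp.m`,
`mcmc.iters`, `mcmc.burn_in`, `seed`, `window_bp`, `n_proc`), validated
on load with unknown keys rejected, and echoed both to the log and to a
per-run `manifest.json`. The config file format is JSON rather than YAML:
the package deliberately depends only on libraries available in a plain
scientific R stack, and `jsonlite` is already required for pattern
serialization. One seed drives all randomness.

# Known limitations

* Hyperparameters (`kappa`, `m`) are fixed, not sampled; there is no
  integration over the prior's hyperparameters (full INLA) and no
  split-merge moves. For the intended scale (tens of proteins) the
  collapsed single-protein Gibbs moves mix well; strongly multimodal
  partition posteriors at larger `N` would benefit from split-merge.
* The Laplace evidence is an approximation; its error is well below the
  evidence differences observed in practice but is not controlled
  adaptively.
* One peak file per protein: replicate merging is upstream of this tool.
* The common-interval embedding destroys within-window genomic distance
  information across window boundaries by construction; the method
  clusters *state-wide* binding profiles, not local peak geometry.
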
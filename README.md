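# lgcpclust

Nonparametric Bayesian clustering of proteins by their ChIP-seq
binding-site point patterns within chromatin states.

## The problem

Transcription factors and other chromatin proteins act in combinatorial
modules, and which partners co-bind depends on chromatin context: a factor
may share targets with one set of proteins in broad promoters and a
different set in poised enhancers. Given (a) one ChIP-seq peak file per
protein and (b) a chromatin-state segmentation of the genome (e.g. diHMM
domain-level states), `lgcpclust` asks, *within one chromatin state*, which
proteins place their binding events in the same spatial pattern — and
groups them into candidate regulatory modules without fixing the number of
clusters in advance.

## The model

All genome windows of one domain-level state are concatenated (natural
chromosome order) and rescaled to a common interval [0, L] with L = 50.
Each peak is reduced to its center, a single binding event, so protein *i*
contributes a point pattern S\_i on [0, L] modeled as an inhomogeneous
Poisson process with intensity λ\_i(s):

    f(S_i | λ_i) = exp(−∫ λ_i(s) ds) · ∏_j λ_i(s_ij)

The log-intensities are clustered with a Dirichlet process mixture of
log-Gaussian Cox processes:

    S_i | λ_i  ~  IPP(λ_i),    log λ_i = z_i,    z_i ~ G,    G ~ DP(m, G0)

where `m` is the DP precision and the base measure G0 is a mean-zero
Gaussian field, discretized on a regular B-bin grid as a second-order
random-walk (RW2) Gaussian Markov random field with precision
`κ·D2ᵀD2 + ridge·I`. Proteins in the same mixture component share one
intensity function. Cluster marginal likelihoods are computed by a Laplace
approximation (sparse Newton solve on the grid), and the posterior over
partitions is explored with a collapsed Gibbs sampler in the style of
Neal's Algorithm 3: protein *i* joins cluster *c* with probability
∝ n\_c · exp[Λ(c∪i) − Λ(c)], or opens a new cluster with probability
∝ m · exp[Λ({i})], where Λ is the Laplace log marginal evidence.

Outputs are the per-iteration partitions, the pairwise **co-binding
probability matrix** (frequency with which two proteins share a cluster
across the stored MCMC iterations, 200 by default), a consensus partition
(Dahl's least-squares rule on the co-binding matrix), and per-cluster
intensity curves. A seeded K-means-on-intensity-curves baseline with
silhouette model selection is included for comparison, as are downstream
utilities: peak-in-state log2 enrichment, ±2 kb TSS-proximal gene
assignment, and TPM expression summaries per protein or module.

## Worked example

Six synthetic proteins drawn from three known intensity archetypes
(Gaussian bumps at 10/25/40 on [0, 50], ~150 events each), clustered with
the default configuration:

```r
library(lgcpclust)
sim     <- make_scenario(N = 6, seed = 42)      # truth: 1,2,3,1,2,3
grid    <- grid_spec(100, 50)
samples <- run_mcmc(sim$patterns, grid, n_iter = 200, seed = 7)
consensus_partition(samples)
#> proc01 proc02 proc03 proc04 proc05 proc06
#>      1      2      3      1      2      3
round(samples$cobinding, 2)
#>        proc01 proc02 proc03 proc04 proc05 proc06
#> proc01      1      0      0      1      0      0
#> proc02      0      1      0      0      1      0
#> proc03      0      0      1      0      0      1
#> proc04      1      0      0      1      0      0
#> proc05      0      1      0      0      1      0
#> proc06      0      0      1      0      0      1
adjusted_rand_index(consensus_partition(samples), sim$scenario$labels)
#> [1] 1
```

The consensus recovers the three planted modules exactly (adjusted Rand
index 1), and the co-binding matrix shows posterior probability 1 for the
planted pairs and 0 elsewhere: every stored iteration agreed on the
partition. `estimate_intensity(sim$patterns[consensus == 1], grid)` then
gives the shared binding-intensity curve of a module (here peaking at
25.3 events/unit near s = 8.75, the planted bump at 10).

For real data, start from peak files and a segmentation instead:

```r
seg  <- read_segmentation("domain_states.bed")
cmap <- build_coordinate_map(seg, "D5")          # one chromatin state
pats <- lapply(list.files("peaks", full.names = TRUE), function(f) {
  ps <- read_peaks(f, dialect = "narrowPeak")
  project_peaks(peak_centers(ps), cmap, protein = ps$protein)
})
samples <- run_mcmc(pats, grid_spec(100, 50), n_iter = 200, seed = 1)
```

## Command line

A pipeline driver is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "lgcpclust", package = "lgcpclust"))')
Rscript $CLI simulate --out sim/ --seed 4
Rscript $CLI project  --peaks sim/fixtures --segmentation sim/fixtures/segmentation.bed \
                      --state D5 --out patterns.json
Rscript $CLI cluster  --patterns sim/patterns.json --iters 200 --seed 7 --out run/
Rscript $CLI enrich   --peaks sim/fixtures/TFA.bed \
                      --segmentation sim/fixtures/segmentation.bed \
                      --genome-bp 20000 --out enrichment.tsv
```

`cluster` writes `partitions.tsv`, `cobinding.tsv`, `consensus.tsv`,
`cluster_intensity.tsv`, a per-iteration chain log, and a `manifest.json`
recording every resolved parameter. Configuration is a flat JSON file
(`--config`) with CLI overrides; unknown keys are rejected.

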
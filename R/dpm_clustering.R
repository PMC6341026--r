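# Dirichlet-process mixture sampler over partitions of N proteins.
#
# Collapsed Gibbs reassignment in the style of Neal's Algorithm 3: the
# latent intensity of each cluster is marginalized by the Laplace
# approximation, so a protein joins an existing cluster c with probability
# proportional to n_c * exp(L(c + i) - L(c)) and opens a new cluster with
# probability proportional to m * exp(L({i})), where L is the cluster log
# marginal likelihood and m the DP precision.

#' Construct a ClusterState
#'
#' @param assignment integer vector of cluster ids (one per protein);
#'   ids are normalized to 1..K in order of first appearance.
#' @param m DP precision parameter (> 0).
#' @return object of class `ClusterState`: list with `assignment`,
#'   `clusters` (list id -> member indices), `m`, `K`.
#' @export
cluster_state <- function(assignment, m = 1) {
  stopifnot_scalar_number(m, "m", positive = TRUE)
  assignment <- as.integer(assignment)
  if (!length(assignment) || anyNA(assignment))
    abort("assignment must be a non-empty integer vector")
  assignment <- match(assignment, unique(assignment))
  clusters <- split(seq_along(assignment), assignment)
  structure(list(assignment = assignment, clusters = unname(clusters),
                 m = m, K = length(clusters)),
            class = "ClusterState")
}

#' @export
print.ClusterState <- function(x, ...) {
  cat(sprintf("ClusterState: N = %d, K = %d, m = %g\n",
              length(x$assignment), x$K, x$m))
  invisible(x)
}

# canonical relabeling by order of first appearance
canonical_assignment <- function(assignment) {
  match(assignment, unique(assignment))
}

#' One collapsed Gibbs sweep over all proteins
#'
#' Each protein in turn is removed from its cluster (empty clusters are
#' deleted) and reassigned with log-weights `log n_c + L(c + i) - L(c)`
#' for existing clusters and `log m + L({i})` for a new one; weights are
#' max-shifted before exponentiation. Uses R's global RNG stream.
#'
#' @param state a [cluster_state()].
#' @param evidence either a function(member_indices) -> log marginal (see
#'   [cluster_evidence()]), or a list of [point_pattern()]s from which one
#'   is built (rebuilt every call — prefer passing the function in loops).
#' @param grid,theta used only when `evidence` is a pattern list.
#' @return the updated [cluster_state()].
#' @export
gibbs_sweep <- function(state, evidence, grid = grid_spec(),
                        theta = lgcp_theta()) {
  stopifnot(inherits(state, "ClusterState"))
  if (!is.function(evidence))
    evidence <- cluster_evidence(evidence, grid, theta)
  assignment <- state$assignment
  m <- state$m
  N <- length(assignment)
  for (i in seq_len(N)) {
    ids <- sort(unique(assignment[-i]))
    clusters <- lapply(ids, function(id)
      setdiff(which(assignment == id), i))
    K <- length(clusters)
    logw <- numeric(K + 1L)
    for (k in seq_len(K)) {
      members <- clusters[[k]]
      logw[k] <- log(length(members)) +
        evidence(c(members, i)) - evidence(members)
    }
    logw[K + 1L] <- log(m) + evidence(i)
    if (any(!is.finite(logw)))
      abort(sprintf("non-finite reassignment weight for protein %d (cluster %s)",
                    i, paste(which(!is.finite(logw)), collapse = ",")))
    w <- exp(logw - max(logw))
    pick <- sample.int(K + 1L, 1L, prob = w)
    assignment[i] <- if (pick <= K) ids[pick]
                     else if (K == 0L) 1L else max(ids) + 1L
  }
  cluster_state(assignment, m = m)
}

#' Run the DP mixture MCMC chain
#'
#' Starts from all singletons, performs `n_iter` collapsed Gibbs sweeps
#' with a seeded generator, stores every post-burn-in partition, and logs
#' the number of occupied clusters and the joint log-score (CRP prior
#' kernel plus summed cluster evidences) per iteration.
#'
#' @param patterns list of [point_pattern()]s (one per protein).
#' @param grid a [grid_spec()].
#' @param theta a [lgcp_theta()].
#' @param m DP precision (default 1).
#' @param n_iter total Gibbs sweeps (default 200, the standard chain
#'   length here).
#' @param burn_in sweeps discarded before storage (default 0: co-binding
#'   frequencies are computed over the full chain).
#' @param seed integer seed for R's RNG.
#' @param evidence optional evidence function overriding the
#'   Laplace-approximate [cluster_evidence()]; e.g. `function(members) 0`
#'   gives a flat likelihood so the chain samples the CRP prior.
#' @return object of class `PosteriorSamples`: list with `partitions`
#'   (matrix, stored iterations x N, canonical labels), `n_iter`,
#'   `burn_in`, `cobinding` (N x N co-assignment frequency matrix),
#'   `proteins`, `K_trace`, `log_score_trace`, `m`, `seed`.
#' @export
run_mcmc <- function(patterns, grid = grid_spec(), theta = lgcp_theta(),
                     m = 1, n_iter = 200L, burn_in = 0L, seed = 1L,
                     evidence = NULL) {
  n_iter <- as.integer(n_iter)
  burn_in <- as.integer(burn_in)
  if (n_iter <= burn_in || burn_in < 0L)
    abort("need n_iter > burn_in >= 0")
  patterns <- as_pattern_list(patterns)
  N <- length(patterns)
  proteins <- vapply(patterns, `[[`, character(1), "protein")
  if (is.null(evidence)) evidence <- cluster_evidence(patterns, grid, theta)
  set.seed(as.integer(seed))
  state <- cluster_state(seq_len(N), m = m)
  n_stored <- n_iter - burn_in
  partitions <- matrix(NA_integer_, n_stored, N,
                       dimnames = list(NULL, proteins))
  K_trace <- integer(n_iter)
  score_trace <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    state <- gibbs_sweep(state, evidence)
    K_trace[it] <- state$K
    score_trace[it] <- joint_log_score(state, evidence)
    if (it > burn_in)
      partitions[it - burn_in, ] <- canonical_assignment(state$assignment)
  }
  samples <- structure(list(partitions = partitions, n_iter = n_iter,
                            burn_in = burn_in, cobinding = NULL,
                            proteins = proteins, K_trace = K_trace,
                            log_score_trace = score_trace, m = m,
                            seed = as.integer(seed)),
                       class = "PosteriorSamples")
  samples$cobinding <- cobinding_matrix(samples)
  samples
}

# unnormalized log p(partition, data): CRP kernel + summed evidences
joint_log_score <- function(state, evidence) {
  sum(vapply(state$clusters, function(members)
    log(state$m) + lgamma(length(members)) + evidence(members),
    numeric(1)))
}

#' @export
print.PosteriorSamples <- function(x, ...) {
  cat(sprintf(
    "PosteriorSamples: %d stored partitions (%d iterations, burn-in %d), N = %d\n",
    nrow(x$partitions), x$n_iter, x$burn_in, length(x$proteins)))
  invisible(x)
}

#' Pairwise co-binding probability matrix
#'
#' Entry (i, j) is the fraction of stored partitions in which proteins i
#' and j share a cluster — symmetric, unit diagonal, values in \[0, 1\].
#'
#' @param samples a [run_mcmc()] result, or a matrix of partitions
#'   (iterations x proteins).
#' @return N x N numeric matrix with protein dimnames when available.
#' @export
cobinding_matrix <- function(samples) {
  partitions <- if (inherits(samples, "PosteriorSamples"))
    samples$partitions else as.matrix(samples)
  if (!nrow(partitions)) abort("need at least one stored partition")
  N <- ncol(partitions)
  cob <- matrix(0, N, N)
  for (t in seq_len(nrow(partitions))) {
    a <- partitions[t, ]
    cob <- cob + outer(a, a, "==")
  }
  cob <- cob / nrow(partitions)
  dimnames(cob) <- list(colnames(partitions), colnames(partitions))
  cob
}

#' Consensus partition (Dahl's least-squares rule)
#'
#' Returns the stored partition minimizing
#' `sum_{i<j} (I[c_i = c_j] - cobinding[i, j])^2`; ties are broken by the
#' earliest stored iteration.
#'
#' @param samples a [run_mcmc()] result.
#' @return integer assignment vector (canonical labels) named by protein.
#' @export
consensus_partition <- function(samples) {
  stopifnot(inherits(samples, "PosteriorSamples"))
  partitions <- samples$partitions
  if (!nrow(partitions)) abort("need at least one stored partition")
  cob <- samples$cobinding %||% cobinding_matrix(partitions)
  loss <- vapply(seq_len(nrow(partitions)), function(t) {
    a <- partitions[t, ]
    d <- outer(a, a, "==") - cob
    sum(d[upper.tri(d)]^2)
  }, numeric(1))
  best <- which.min(loss)  # which.min takes the earliest minimizer
  out <- canonical_assignment(partitions[best, ])
  names(out) <- colnames(partitions)
  out
}

#' K-means baseline on estimated intensity curves
#'
#' Clusters the rows of an intensity matrix (proteins x bins) with
#' seeded K-means; `k = "auto"` selects k in 2..min(8, N-1) by maximum
#' mean silhouette width (Euclidean distance).
#'
#' @param intensity_matrix numeric matrix, one estimated intensity curve
#'   per protein row.
#' @param k integer number of clusters, or `"auto"`.
#' @param seed seed for the K-means initialization.
#' @param nstart random restarts passed to [stats::kmeans()].
#' @return integer assignment vector (canonical labels), named by rownames.
#' @export
kmeans_baseline <- function(intensity_matrix, k = "auto", seed = 1L,
                            nstart = 10L) {
  X <- as.matrix(intensity_matrix)
  N <- nrow(X)
  if (N < 2L) abort("need at least 2 intensity curves")
  if (all(apply(X, 2, function(col) length(unique(col)) == 1L))) {
    warning("all intensity curves identical; returning a single cluster")
    return(stats::setNames(rep(1L, N), rownames(X)))
  }
  set.seed(as.integer(seed))
  fit_k <- function(k) stats::kmeans(X, centers = k, nstart = nstart)
  if (identical(k, "auto")) {
    ks <- 2:min(8L, N - 1L)
    d <- stats::dist(X)
    sil <- vapply(ks, function(kk) {
      cl <- fit_k(kk)$cluster
      mean(cluster::silhouette(cl, d)[, "sil_width"])
    }, numeric(1))
    k <- ks[which.max(sil)]
  }
  k <- as.integer(k)
  if (k < 1L || k > N) abort("k must be in 1..N")
  cl <- if (k == N) seq_len(N) else if (k == 1L) rep(1L, N)
        else fit_k(k)$cluster
  stats::setNames(canonical_assignment(cl), rownames(X))
}

#' Adjusted Rand index between two partitions
#'
#' Standard Hubert–Arabie adjustment; 1 for identical partitions, about 0
#' for independent ones.
#'
#' @param a,b integer/factor assignment vectors of equal length.
#' @return scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
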
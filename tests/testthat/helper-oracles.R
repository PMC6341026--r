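# Independent oracles used by the unit and acceptance tests. Nothing here
# calls into the package's own Laplace/Newton code paths: the quadrature
# oracle re-derives the integrand from scratch and integrates it with
# adaptive Gauss-Hermite quadrature; partition enumeration and CRP
# probabilities are closed-form.

# --- Gauss-Hermite nodes/weights (Golub-Welsch on the Jacobi matrix) ----
gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- diag(0, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# log of sum(exp(x)) without overflow
log_sum_exp <- function(x) {
  mx <- max(x)
  mx + log(sum(exp(x - mx)))
}

# Log marginal likelihood of gridded Poisson counts under a Gaussian(0, Q^-1)
# prior on z, by adaptive tensor Gauss-Hermite quadrature:
#   log integral exp{ sum_b [c_b (mean0+z_b) - e_b exp(mean0+z_b)] } N(z; 0, Q^-1) dz
# The likelihood carries no factorial term, matching the continuous
# inhomogeneous-Poisson likelihood of distinguishable events.
# Mode/curvature for the affine change of variables come from stats::optim/
# optimHess on an independently written objective.
quadrature_log_marginal <- function(counts, exposure, Q, mean0, nodes = 16L) {
  B <- length(counts)
  Q <- as.matrix(Q)
  chQ <- chol(Q)
  log_det_Q <- 2 * sum(log(diag(chQ)))
  gfun <- function(z) {
    eta <- mean0 + z
    sum(counts * eta - exposure * exp(eta)) -
      0.5 * B * log(2 * pi) + 0.5 * log_det_Q -
      0.5 * sum(z * (Q %*% z))
  }
  opt <- stats::optim(numeric(B), function(z) -gfun(z), method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
  mode <- opt$par
  H <- stats::optimHess(mode, function(z) -gfun(z))
  R <- chol((H + t(H)) / 2)
  Rinv <- backsolve(R, diag(B))
  gh <- gauss_hermite(nodes)
  grids <- rep(list(seq_len(nodes)), B)
  idx <- as.matrix(expand.grid(grids))
  X <- matrix(gh$nodes[idx], ncol = B)
  logw <- rowSums(matrix(log(gh$weights)[idx], ncol = B))
  Z <- sqrt(2) * X %*% t(Rinv)
  Z <- sweep(Z, 2, mode, "+")
  eta <- sweep(Z, 2, rep(mean0, B), "+")
  loglik <- as.numeric(Z %*% counts) + mean0 * sum(counts) -
    as.numeric(exp(eta) %*% exposure)
  logprior <- -0.5 * B * log(2 * pi) + 0.5 * log_det_Q -
    0.5 * rowSums((Z %*% Q) * Z)
  g <- loglik + logprior
  0.5 * B * log(2) - sum(log(diag(R))) +
    log_sum_exp(logw + g + rowSums(X^2))
}

# --- set partitions ------------------------------------------------------
# all set partitions of 1..n as canonical assignment vectors (labels in
# order of first appearance)
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    K <- max(p)
    for (k in seq_len(K + 1L)) out[[length(out) + 1L]] <- c(p, k)
  }
  out
}

partition_key <- function(assignment) {
  paste(match(assignment, unique(assignment)), collapse = ".")
}

# closed-form CRP probability of a partition: m^K prod(n_c - 1)! / prod_{t}(m + t - 1)
crp_log_prob <- function(assignment, m) {
  n <- length(assignment)
  sizes <- tabulate(match(assignment, unique(assignment)))
  length(sizes) * log(m) + sum(lgamma(sizes)) -
    sum(log(m + seq_len(n) - 1))
}

# --- misc ----------------------------------------------------------------
# brute-force projection of a single center through a coordinate map,
# written against the mapping definition (not the package loop)
brute_force_project <- function(chrom, position, windows, L) {
  total_bp <- sum(windows$end - windows$start)
  off <- 0
  for (k in seq_len(nrow(windows))) {
    w <- windows[k, ]
    if (chrom == w$chrom && position >= w$start && position < w$end)
      return((off + position - w$start) * L / total_bp)
    off <- off + (w$end - w$start)
  }
  NA_real_
}

# inversion sampler for an inhomogeneous Poisson process: n ~ Poisson(mass),
# locations iid from the normalized intensity via numerical inverse CDF
inversion_sample_ipp <- function(intensity, L, n_events) {
  s <- seq(0, L, length.out = 20001L)
  f <- intensity(s)
  cdf <- cumsum((f[-1] + f[-length(f)]) / 2 * diff(s))
  cdf <- c(0, cdf) / max(cdf)
  stats::approx(cdf, s, xout = stats::runif(n_events), ties = "ordered")$y
}

# numerical integral of an intensity over [0, L] (trapezoid, fine grid)
intensity_mass <- function(intensity, L) {
  s <- seq(0, L, length.out = 20001L)
  f <- intensity(s)
  sum((f[-1] + f[-length(f)]) / 2 * diff(s))
}

# normalized-intensity CDF as a vectorized function (for ks.test)
intensity_cdf_fun <- function(intensity, L) {
  s <- seq(0, L, length.out = 20001L)
  f <- intensity(s)
  cdf <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(s)))
  cdf <- cdf / max(cdf)
  function(q) stats::approx(s, cdf, xout = pmin(pmax(q, 0), L),
                            rule = 2, ties = "ordered")$y
}

# small toy pattern builders used across tests
toy_pattern <- function(events, protein = "p", L = 50)
  point_pattern(events, protein = protein, state = "toy", L = L)
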
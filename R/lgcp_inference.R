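# Log-Gaussian Cox process intensity estimation on a regular grid.
#
# The continuous inhomogeneous-Poisson likelihood is discretized as
# independent Poisson counts per grid bin,
#     counts_b ~ Poisson(exposure_b * exp(mean0 + z_b)),
# with exposure_b = (number of pooled processes) * bin width, and the
# latent log-intensity z carries a second-order random-walk (RW2) GMRF
# prior with sparse precision Q = kappa * D2'D2 + ridge * I. The posterior
# mode is found by Newton iterations; the Laplace approximation of the log
# marginal likelihood is the evidence the Dirichlet-process sampler uses.

#' Regular grid over the common interval
#'
#' @param B number of bins (>= 4).
#' @param L interval length.
#' @return object of class `GridSpec`: list with `B`, `L`,
#'   `delta = L / B` and bin `midpoints`.
#' @export
grid_spec <- function(B = 100L, L = 50) {
  stopifnot_scalar_number(L, "L", positive = TRUE)
  B <- as.integer(B)
  if (is.na(B) || B < 4L) abort("B must be an integer >= 4")
  delta <- L / B
  structure(list(B = B, L = L, delta = delta,
                 midpoints = (seq_len(B) - 0.5) * delta),
            class = "GridSpec")
}

#' Default LGCP prior hyperparameters
#'
#' `kappa` scales the RW2 smoothness precision; `ridge` is a small diagonal
#' addition making the (otherwise rank-deficient) RW2 precision proper.
#'
#' @param kappa positive precision scale (default 1).
#' @param ridge positive diagonal ridge (default 1e-8).
#' @return list with `kappa` and `ridge`.
#' @export
lgcp_theta <- function(kappa = 1, ridge = 1e-8) {
  stopifnot_scalar_number(kappa, "kappa", positive = TRUE)
  stopifnot_scalar_number(ridge, "ridge", positive = TRUE)
  list(kappa = kappa, ridge = ridge)
}

as_pattern_list <- function(patterns) {
  if (inherits(patterns, "PointPattern")) return(list(patterns))
  stopifnot(is.list(patterns), length(patterns) >= 1L,
            all(vapply(patterns, inherits, logical(1), "PointPattern")))
  patterns
}

#' Bin point-pattern events on a grid
#'
#' Bins are half-open `[lo, hi)` except the last, which is closed so an
#' event at exactly `L` is counted. Pooling r patterns sums their counts
#' and sets every bin's exposure to `delta * r`.
#'
#' @param patterns a [point_pattern()] or list of them (pooled).
#' @param grid a [grid_spec()].
#' @return list with integer `counts` (length B), numeric `exposure`
#'   (length B) and `r`, the number of pooled processes.
#' @export
bin_events <- function(patterns, grid) {
  stopifnot(inherits(grid, "GridSpec"))
  patterns <- as_pattern_list(patterns)
  events <- unlist(lapply(patterns, `[[`, "events"), use.names = FALSE)
  if (length(events) && (min(events) < 0 || max(events) > grid$L))
    abort(sprintf("event outside [0, %g]", grid$L))
  idx <- pmin(floor(events / grid$delta) + 1L, grid$B)
  counts <- tabulate(idx, nbins = grid$B)
  r <- length(patterns)
  list(counts = counts, exposure = rep(r * grid$delta, grid$B), r = r)
}

#' RW2 GMRF prior precision matrix
#'
#' Returns the sparse symmetric positive-definite matrix
#' `kappa * t(D2) %*% D2 + ridge * I`, where `D2` is the
#' `(B-2) x B` second-difference operator.
#'
#' @param theta a [lgcp_theta()].
#' @param B number of grid bins.
#' @return a sparse symmetric `Matrix` of dimension `B x B`.
#' @export
build_prior_precision <- function(theta, B) {
  stopifnot_scalar_number(theta$kappa, "kappa", positive = TRUE)
  B <- as.integer(B)
  if (B < 4L) abort("B must be >= 4")
  D2 <- Matrix::bandSparse(B - 2L, B, k = 0:2,
                           diagonals = list(rep(1, B - 2L), rep(-2, B - 2L),
                                            rep(1, B - 2L)))
  Q <- theta$kappa * Matrix::crossprod(D2) +
    theta$ridge * Matrix::Diagonal(B)
  Matrix::forceSymmetric(Q)
}

#' Laplace fit of the gridded LGCP posterior
#'
#' Maximizes the penalized Poisson log-likelihood
#' `sum_b [counts_b * (mean0 + z_b) - exposure_b * exp(mean0 + z_b)] -
#'  z' Q z / 2` by Newton iterations (with step-halving safeguard), and
#' returns the Laplace approximation of the log marginal likelihood
#' `loglik(zhat) + logprior(zhat) + (B/2) log 2pi - logdet(H)/2`,
#' where `H = Q + diag(exposure * exp(mean0 + zhat))` is the posterior
#' curvature.
#'
#' The likelihood deliberately carries no `log(counts!)` normalizer: it is
#' the gridded form of the continuous inhomogeneous-Poisson likelihood
#' `prod_j lambda(s_j) * exp(-integral lambda)`, whose events are
#' distinguishable points. The factorial differs between pooled counts and
#' summed per-member factorials, so including it would bias every
#' merge/split comparison the Dirichlet-process sampler makes.
#'
#' @param counts integer bin counts (length B).
#' @param exposure per-bin exposure (length B).
#' @param prior sparse SPD precision from [build_prior_precision()].
#' @param mean0 fixed prior mean level of the log-intensity.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum Newton iterations.
#' @return object of class `LaplaceFit`: list with `mode`, `mean0`,
#'   `log_marginal`, `log_det_post`, `counts`, `exposure`, `grad_norm`,
#'   `iterations`.
#' @export
laplace_fit <- function(counts, exposure, prior, mean0,
                        tol = 1e-8, max_iter = 100L) {
  B <- length(counts)
  stopifnot(length(exposure) == B, all(dim(prior) == B))
  stopifnot_scalar_number(mean0, "mean0")
  if (any(counts < 0) || any(exposure <= 0))
    abort("counts must be >= 0 and exposure > 0")
  Q <- prior
  z <- numeric(B)

  obj <- function(z) {
    eta <- mean0 + z
    mu <- exposure * exp(eta)
    sum(counts * eta - mu) - 0.5 * sum(z * as.numeric(Q %*% z))
  }

  f <- obj(z)
  grad_norm <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    mu <- exposure * exp(mean0 + z)
    grad <- counts - mu - as.numeric(Q %*% z)
    grad_norm <- max(abs(grad))
    if (grad_norm < tol) break
    H <- Q + Matrix::Diagonal(B, x = mu)
    step <- as.numeric(Matrix::solve(H, grad))
    # step-halving keeps Newton monotone when counts are extreme; the
    # acceptance slack is relative to |f| so rounding noise near the mode
    # cannot reject the full quadratic-basin step
    alpha <- 1
    slack <- 1e-10 * max(1, abs(f))
    repeat {
      f_new <- obj(z + alpha * step)
      if (is.finite(f_new) && f_new >= f - slack) break
      alpha <- alpha / 2
      if (alpha < 1e-10)
        abort(sprintf("Laplace Newton line search failed (|grad| = %g)",
                      grad_norm))
    }
    z <- z + alpha * step
    f <- f_new
  }
  mu <- exposure * exp(mean0 + z)
  grad <- counts - mu - as.numeric(Q %*% z)
  grad_norm <- max(abs(grad))
  if (grad_norm >= tol)
    abort(sprintf("Laplace fit did not converge in %d iterations (|grad| = %g)",
                  max_iter, grad_norm))

  H <- Matrix::forceSymmetric(Q + Matrix::Diagonal(B, x = mu))
  log_det_post <- 2 * Matrix::determinant(Matrix::chol(H))$modulus[1]
  log_det_Q <- 2 * Matrix::determinant(Matrix::chol(Q))$modulus[1]
  eta <- mean0 + z
  loglik <- sum(counts * eta - mu)
  logprior <- -0.5 * B * log(2 * pi) + 0.5 * log_det_Q -
    0.5 * sum(z * as.numeric(Q %*% z))
  log_marginal <- loglik + logprior + 0.5 * B * log(2 * pi) -
    0.5 * log_det_post
  structure(list(mode = z, mean0 = mean0, log_marginal = log_marginal,
                 log_det_post = log_det_post, counts = counts,
                 exposure = exposure, grad_norm = grad_norm,
                 iterations = iter),
            class = "LaplaceFit")
}

# mean0 matched to the observed event rate; flat 1/L fallback with no events
default_mean0 <- function(counts, exposure, L) {
  total <- sum(counts)
  if (total > 0) log(total / sum(exposure)) else log(1 / L)
}

#' Estimate an intensity curve from one or more point patterns
#'
#' Pools the patterns, fits the Laplace posterior mode and returns
#' `exp(mean0 + zhat)` at the grid midpoints. With exposure
#' `delta * r`, the curve is a per-process intensity (events per unit
#' length per process), so pooling identical patterns leaves it unchanged.
#'
#' @param patterns a [point_pattern()] or list of them.
#' @param grid a [grid_spec()].
#' @param theta a [lgcp_theta()].
#' @return numeric vector of length `grid$B`; attribute `"fit"` carries
#'   the underlying [laplace_fit()].
#' @export
estimate_intensity <- function(patterns, grid, theta = lgcp_theta()) {
  binned <- bin_events(patterns, grid)
  prior <- build_prior_precision(theta, grid$B)
  mean0 <- default_mean0(binned$counts, binned$exposure, grid$L)
  fit <- laplace_fit(binned$counts, binned$exposure, prior, mean0)
  structure(exp(mean0 + fit$mode), fit = fit)
}

#' Laplace log marginal likelihood of a candidate cluster
#'
#' The evidence that the member patterns share one latent intensity:
#' the Laplace-approximate `log p(pooled counts)` under a single shared
#' GMRF field. Deterministic in its inputs; invariant to member order.
#'
#' @param member_patterns list of [point_pattern()]s (>= 1).
#' @param grid a [grid_spec()].
#' @param theta a [lgcp_theta()].
#' @param cache optional environment; results are memoized under the
#'   sorted member-name key.
#' @return scalar log marginal likelihood.
#' @export
cluster_log_marginal <- function(member_patterns, grid,
                                 theta = lgcp_theta(), cache = NULL) {
  member_patterns <- as_pattern_list(member_patterns)
  key <- NULL
  if (!is.null(cache)) {
    key <- paste(sort(vapply(member_patterns, `[[`, character(1), "protein")),
                 collapse = "\r")
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  binned <- bin_events(member_patterns, grid)
  prior <- build_prior_precision(theta, grid$B)
  mean0 <- default_mean0(binned$counts, binned$exposure, grid$L)
  lm <- laplace_fit(binned$counts, binned$exposure, prior, mean0)$log_marginal
  if (!is.null(key)) cache[[key]] <- lm
  lm
}

#' Memoized cluster-evidence function over indexed patterns
#'
#' Pre-bins each pattern once and returns a closure mapping a vector of
#' member indices to the cluster's Laplace log marginal likelihood, with
#' results cached by member set. This is the evidence the Gibbs sampler
#' calls thousands of times per chain.
#'
#' @param patterns list of [point_pattern()]s.
#' @param grid a [grid_spec()].
#' @param theta a [lgcp_theta()].
#' @return function(member_indices) -> log marginal (scalar).
#' @export
cluster_evidence <- function(patterns, grid, theta = lgcp_theta()) {
  patterns <- as_pattern_list(patterns)
  count_mat <- vapply(patterns, function(p) bin_events(p, grid)$counts,
                      integer(grid$B))  # B x N
  prior <- build_prior_precision(theta, grid$B)
  L <- grid$L
  delta <- grid$delta
  B <- grid$B
  cache <- new.env(parent = emptyenv())
  function(members) {
    members <- sort(as.integer(members))
    key <- paste(members, collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    counts <- if (length(members) == 1L) count_mat[, members]
              else as.integer(rowSums(count_mat[, members, drop = FALSE]))
    exposure <- rep(length(members) * delta, B)
    mean0 <- default_mean0(counts, exposure, L)
    lm <- laplace_fit(counts, exposure, prior, mean0)$log_marginal
    cache[[key]] <- lm
    lm
  }
}

#' Export intensity curves as TSV
#'
#' @param curves matrix (proteins x bins) or single numeric curve.
#' @param grid a [grid_spec()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity_tsv <- function(curves, grid, path) {
  if (is.null(dim(curves))) curves <- matrix(curves, nrow = 1)
  df <- data.frame(midpoint = grid$midpoints, t(curves))
  names(df)[-1] <- rownames(curves) %||% paste0("curve", seq_len(nrow(curves)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
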
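flat_evidence <- function(members) 0

test_that("cluster_state normalizes ids and tracks K", {
  st <- cluster_state(c(5L, 5L, 2L, 9L), m = 0.5)
  expect_equal(st$assignment, c(1L, 1L, 2L, 3L))
  expect_equal(st$K, 3L)
  expect_equal(sort(unlist(st$clusters)), 1:4)
  expect_error(cluster_state(1:3, m = 0), "positive")
})

test_that("gibbs_sweep is identity for N = 1 and merges identical data", {
  st <- cluster_state(1L)
  set.seed(1)
  expect_equal(gibbs_sweep(st, flat_evidence)$assignment, 1L)

  # two identical patterns, m -> 0+: both in one cluster almost surely
  g <- grid_spec(50, 50)
  set.seed(2)
  pp <- toy_pattern(runif(80, 10, 20), "a")
  pp2 <- toy_pattern(pp$events, "b")
  ev <- cluster_evidence(list(pp, pp2), g)
  st <- cluster_state(c(1L, 2L), m = 1e-8)
  set.seed(3)
  together <- vapply(1:50, function(i) {
    st <<- gibbs_sweep(st, ev)
    st$K == 1L
  }, logical(1))
  expect_gte(mean(together), 0.98)
})

test_that("non-finite evidence is reported with the protein index", {
  bad_ev <- function(members) if (length(members) > 1) NaN else 0
  st <- cluster_state(c(1L, 2L))
  set.seed(1)
  expect_error(gibbs_sweep(st, bad_ev), "non-finite.*protein")
})

test_that("run_mcmc is deterministic given a seed and stores every sweep", {
  sim <- make_scenario(N = 4L, seed = 10)
  g <- grid_spec(20, 50)
  s1 <- run_mcmc(sim$patterns, g, n_iter = 15, seed = 42)
  s2 <- run_mcmc(sim$patterns, g, n_iter = 15, seed = 42)
  expect_identical(s1$partitions, s2$partitions)
  expect_identical(s1$K_trace, s2$K_trace)
  expect_equal(nrow(s1$partitions), 15L)
  expect_equal(ncol(s1$partitions), 4L)
  # burn-in discards leading sweeps
  s3 <- run_mcmc(sim$patterns, g, n_iter = 15, burn_in = 5, seed = 42)
  expect_equal(nrow(s3$partitions), 10L)
  expect_identical(s3$partitions, s1$partitions[6:15, , drop = FALSE])
  expect_error(run_mcmc(sim$patterns, g, n_iter = 5, burn_in = 5), "n_iter")
})

test_that("cobinding_matrix matches hand-computed frequencies", {
  partitions <- rbind(c(1L, 1L, 2L, 2L),
                      c(1L, 1L, 1L, 2L),
                      c(1L, 2L, 1L, 2L),
                      c(1L, 1L, 2L, 2L))
  colnames(partitions) <- paste0("p", 1:4)
  cob <- cobinding_matrix(partitions)
  # hand counts out of 4 stored partitions
  expect_equal(cob["p1", "p2"], 3 / 4)
  expect_equal(cob["p1", "p3"], 2 / 4)
  expect_equal(cob["p3", "p4"], 2 / 4)
  expect_equal(cob["p2", "p4"], 1 / 4)
  expect_equal(diag(cob), setNames(rep(1, 4), paste0("p", 1:4)))
  expect_equal(cob, t(cob))
  expect_true(all(cob >= 0 & cob <= 1))
  # invariance to relabeling of cluster ids
  relabeled <- partitions
  relabeled[2, ] <- c(7L, 7L, 7L, 3L)
  expect_equal(unname(cobinding_matrix(relabeled)), unname(cob))
})

test_that("consensus_partition implements Dahl's least-squares rule", {
  one <- matrix(c(1L, 1L, 2L), 1, dimnames = list(NULL, letters[1:3]))
  samples1 <- structure(list(partitions = one, cobinding = NULL),
                        class = "PosteriorSamples")
  samples1$cobinding <- cobinding_matrix(one)
  expect_equal(unname(consensus_partition(samples1)), c(1L, 1L, 2L))

  # strict majority partition wins
  maj <- rbind(c(1L, 1L, 2L), c(1L, 1L, 2L), c(1L, 1L, 2L),
               c(1L, 2L, 2L), c(1L, 2L, 1L))
  colnames(maj) <- letters[1:3]
  samples2 <- structure(list(partitions = maj, cobinding = NULL),
                        class = "PosteriorSamples")
  samples2$cobinding <- cobinding_matrix(maj)
  expect_equal(unname(consensus_partition(samples2)), c(1L, 1L, 2L))
})

test_that("consensus equals the modal partition on a synthetic run", {
  sim <- make_scenario(N = 6L, seed = 3)
  s <- run_mcmc(sim$patterns, grid_spec(50, 50), n_iter = 40, seed = 5)
  keys <- apply(s$partitions, 1, paste, collapse = ".")
  modal <- names(which.max(table(keys)))
  expect_equal(paste(consensus_partition(s), collapse = "."), modal)
})

test_that("kmeans_baseline recovers curve groups and handles edge cases", {
  set.seed(6)
  base1 <- sin(seq(0, pi, length.out = 30))
  base2 <- cos(seq(0, pi, length.out = 30)) + 2
  X <- rbind(t(replicate(4, base1 + rnorm(30, 0, 0.02))),
             t(replicate(4, base2 + rnorm(30, 0, 0.02))))
  rownames(X) <- paste0("p", 1:8)
  cl <- kmeans_baseline(X, k = "auto", seed = 1)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(adjusted_rand_index(cl, rep(1:2, each = 4)), 1)

  # k = N: each row its own cluster
  expect_equal(length(unique(kmeans_baseline(X, k = 8))), 8L)

  # duplicated rows always co-assigned
  X2 <- X
  X2[2, ] <- X2[1, ]
  cl2 <- kmeans_baseline(X2, k = 2, seed = 2)
  expect_equal(cl2[1], cl2[2], ignore_attr = TRUE)

  # degenerate input: single cluster with a warning
  Xd <- matrix(1, 3, 5, dimnames = list(paste0("p", 1:3), NULL))
  expect_warning(cld <- kmeans_baseline(Xd), "identical")
  expect_equal(unname(cld), rep(1L, 3))
})

test_that("expected K is non-decreasing in the DP precision m", {
  sim <- make_scenario(default_archetypes()[1:2], N = 6L, seed = 7)
  g <- grid_spec(20, 50)
  ev <- cluster_evidence(sim$patterns, g)
  mean_K <- vapply(c(0.1, 1, 10), function(m) {
    ks <- vapply(1:20, function(seed) {
      s <- run_mcmc(sim$patterns, g, m = m, n_iter = 20, seed = seed,
                    evidence = ev)
      mean(s$K_trace)
    }, numeric(1))
    mean(ks)
  }, numeric(1))
  expect_lte(mean_K[1], mean_K[2] + 0.05)
  expect_lte(mean_K[2], mean_K[3] + 0.05)
})

test_that("adjusted_rand_index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 10),
                                    rep(c(1, 1, 2, 2), 5))), 0.35)
})
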
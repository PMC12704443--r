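# Cluster-based permutation testing over channel x point grids.

test_that("adjacency from positions is symmetric and irreflexive", {
  mont <- sim_montage(12)
  adj <- adjacency_from_positions(mont)
  expect_true(isSymmetric(adj))
  expect_false(any(diag(adj)))
  expect_true(any(adj))
})

test_that("the paired t map matches t.test on a hand-sized example", {
  set.seed(3)
  a <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  b <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  tm <- paired_t_map(a, b)
  for (ch in 1:2) for (k in 1:3) {
    ref <- t.test(a[, ch, k], b[, ch, k], paired = TRUE)$statistic
    expect_equal(tm[ch, k], unname(ref))
  }
  # identical conditions give an all-zero map with zero-variance flags
  tz <- paired_t_map(a, a)
  expect_true(all(tz == 0))
  expect_true(all(attr(tz, "zero_var")))
})

test_that("mean t grows like sqrt(n) under a constant shift", {
  set.seed(4)
  mt <- vapply(c(8, 32), function(n) {
    a <- array(rnorm(n * 1 * 200, 0.5), c(n, 1, 200))
    b <- array(rnorm(n * 1 * 200, 0), c(n, 1, 200))
    mean(paired_t_map(a, b))
  }, 1.0)
  expect_equal(mt[2] / mt[1], 2, tolerance = 0.2)
})

test_that("clusterize splits by sign and joins by adjacency", {
  adj <- matrix(FALSE, 3, 3)
  adj[1, 2] <- adj[2, 1] <- TRUE          # 3 is isolated
  tm <- matrix(0, 3, 4)
  tm[1, 1] <- 5                            # singleton
  cl <- clusterize(tm, 2, adj)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$stat, 5)
  # same point on non-neighbor channels: two clusters
  tm2 <- matrix(0, 3, 4); tm2[1, 2] <- 4; tm2[3, 2] <- 4
  expect_length(clusterize(tm2, 2, adj), 2)
  # L-shaped region on one channel plus its neighbor: one cluster
  tm3 <- matrix(0, 3, 4); tm3[1, 1:3] <- 3; tm3[2, 3] <- 3
  cl3 <- clusterize(tm3, 2, adj)
  expect_length(cl3, 1)
  expect_equal(cl3[[1]]$stat, 12)
  # opposite signs never merge
  tm4 <- matrix(0, 3, 4); tm4[1, 1] <- 3; tm4[1, 2] <- -3
  expect_length(clusterize(tm4, 2, adj), 2)
})

test_that("clusterize agrees with a brute-force oracle on random grids", {
  set.seed(12)
  for (rep in 1:25) {
    n_ch <- sample(3:6, 1); n_k <- sample(4:10, 1)
    adj <- matrix(FALSE, n_ch, n_ch)
    for (i in seq_len(n_ch - 1)) if (runif(1) < 0.5)
      adj[i, i + 1] <- adj[i + 1, i] <- TRUE
    tm <- matrix(rnorm(n_ch * n_k, 0, 2), n_ch, n_k)
    thr <- 1.5
    mine <- clusterize(tm, thr, adj)
    oracle <- brute_clusters(tm, thr, adj)
    expect_equal(length(mine), length(oracle))
    expect_equal(unname(sort(vapply(mine, function(c) c$stat, 1.0))),
                 unname(sort(vapply(oracle, function(c) c$stat, 1.0))),
                 tolerance = 1e-12)
  }
})

test_that("the compiled max-cluster statistic matches clusterize", {
  set.seed(13)
  mont <- sim_montage(8)
  adj <- adjacency_from_positions(mont)
  for (rep in 1:20) {
    tm <- matrix(rnorm(8 * 15, 0, 1.5), 8, 15)
    cl <- clusterize(tm, 1.8, adj)
    ref <- if (length(cl)) max(abs(vapply(cl, function(c) c$stat, 1.0))) else 0
    got <- selfcaught:::max_cluster_stat(matrix(as.vector(tm), 1), 8, 15,
                                         adj, 1.8)
    expect_equal(got, ref, tolerance = 1e-12)
  }
})

test_that("permutation p-values are deterministic, bounded and symmetric", {
  set.seed(5)
  mont <- sim_montage(8)
  adj <- adjacency_from_positions(mont)
  a <- array(rnorm(10 * 8 * 20, 0.8), c(10, 8, 20))
  b <- array(rnorm(10 * 8 * 20), c(10, 8, 20))
  r1 <- permutation_test(a, b, adj, n_perm = 300, seed = 42)
  r2 <- permutation_test(a, b, adj, n_perm = 300, seed = 42)
  expect_identical(vapply(r1$clusters, `[[`, 1.0, "p"),
                   vapply(r2$clusters, `[[`, 1.0, "p"))
  ps <- vapply(r1$clusters, `[[`, 1.0, "p")
  expect_true(all(ps >= 1 / 301))
  # swapping the conditions flips the sign but keeps the p-values
  r3 <- permutation_test(b, a, adj, n_perm = 300, seed = 42)
  expect_equal(sort(vapply(r3$clusters, `[[`, 1.0, "p")), sort(ps))
})

test_that("an injected parietal deflection is detected as a negative cluster", {
  set.seed(6)
  mont <- sim_montage(16)
  adj <- adjacency_from_positions(mont)
  par_idx <- which(mont$parietal)
  hits <- vapply(1:10, function(k) {
    a <- array(rnorm(12 * 16 * 40), c(12, 16, 40))   # aware
    b <- array(rnorm(12 * 16 * 40), c(12, 16, 40))   # MW
    a[, par_idx, 20:30] <- a[, par_idx, 20:30] - 1.2  # suppression
    res <- permutation_test(a, b, adj, n_perm = 500, seed = 100 + k)
    neg <- Filter(function(cl) cl$sign < 0 && cl$significant, res$clusters)
    length(neg) > 0 &&
      any(vapply(neg, function(cl)
        mean(cl$members[, 1] %in% par_idx) > 0.5, TRUE))
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
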
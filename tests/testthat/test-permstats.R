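test_that("paired t map matches the textbook statistic", {
  set.seed(51)
  A <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  expect_true(all(paired_t_map(A, A) == 0))

  B <- array(rnorm(4 * 2 * 3), c(4, 2, 3))
  tm <- paired_t_map(A, B)
  expect_equal(attr(tm, "df"), 3)
  for (c0 in 1:2) for (t0 in 1:3) {
    expect_equal(tm[c0, t0], oracle_paired_t(A[, c0, t0], B[, c0, t0]),
                 tolerance = 1e-12)
  }

  # zero-variance points are flagged and set to 0
  A2 <- B
  A2[, 1, 1] <- B[, 1, 1] + 1e-30  # machine-degenerate differences
  A2[, 2, 2] <- B[, 2, 2]
  tm2 <- paired_t_map(A2, B)
  expect_equal(tm2[2, 2], 0)
  expect_true(attr(tm2, "degenerate")[2, 2])

  expect_error(paired_t_map(A, array(0, c(4, 2, 2))), "shape")
})

test_that("cluster formation follows the connectivity definition", {
  # single channel, t = [0, 3, 3, 0], critical 2.1: one cluster, mass 6
  tm <- matrix(c(0, 3, 3, 0), 1)
  adj1 <- list(integer(0))
  fc <- form_clusters(tm, adj1, df = 10, alpha = 2 * (1 - pt(2.1, 10)),
                      min_neighbors = 0)
  expect_length(fc$clusters, 1)
  expect_equal(fc$clusters[[1]]$mass, 6)
  expect_equal(fc$clusters[[1]]$sign, 1)

  # two suprathreshold channels that are not neighbours: two clusters
  tm2 <- matrix(c(3, 0, 3), 3, 1)
  adj3 <- list(integer(0), integer(0), integer(0))
  fc2 <- form_clusters(tm2, adj3, df = 10, alpha = 0.05, min_neighbors = 0)
  expect_length(fc2$clusters, 2)

  # make them neighbours through a suprathreshold middle channel: one
  tm3 <- matrix(c(3, 3, 3), 3, 1)
  adj_chain <- list(2L, c(1L, 3L), 2L)
  fc3 <- form_clusters(tm3, adj_chain, df = 10, alpha = 0.05,
                       min_neighbors = 0)
  expect_length(fc3$clusters, 1)
  expect_equal(fc3$clusters[[1]]$mass, 9)

  # opposite signs never join
  tm4 <- matrix(c(3, -3), 1)
  fc4 <- form_clusters(tm4, adj1, df = 10, alpha = 0.05, min_neighbors = 0)
  expect_length(fc4$clusters, 2)
  expect_setequal(vapply(fc4$clusters, `[[`, numeric(1), "sign"), c(-1, 1))
})

test_that("compiled clustering agrees with a flood-fill oracle", {
  labels5 <- c("F3", "Fz", "F4", "C3", "Cz")
  adj <- build_adjacency(labels5)
  df <- 9
  thresh <- qt(0.975, df)
  for (seed in 1:20) {
    set.seed(seed)
    tm <- matrix(rnorm(5 * 20, 0, 2), 5, 20)
    for (mn in c(0, 2)) {
      fc <- form_clusters(tm, adj, df = df, alpha = 0.05,
                          min_neighbors = mn)
      or <- oracle_clusters(tm, thresh, adj$matrix, min_neighbors = mn)
      expect_equal(sort(round(vapply(fc$clusters, `[[`, numeric(1), "mass"),
                              8)),
                   sort(round(vapply(or, `[[`, numeric(1), "mass"), 8)))
      # memberships match up to relabeling
      pkg_cells <- lapply(fc$clusters, function(cl) {
        lapply(seq_len(nrow(cl$members)), function(i) {
          c(cl$members[i, 1], cl$members[i, 2])
        })
      })
      expect_identical(canon_clusters(pkg_cells),
                       canon_clusters(lapply(or, `[[`, "cells")))
    }
  }
})

test_that("identical conditions yield no clusters and valid p handling", {
  set.seed(52)
  A <- array(rnorm(8 * 5 * 30), c(8, 5, 30))
  adj <- build_adjacency(c("F3", "Fz", "F4", "C3", "Cz"))
  res <- cluster_permutation_test(A, A, adj, n_perm = 200, seed = 1)
  expect_equal(nrow(res$clusters), 0)
  expect_warning(cluster_permutation_test(A, A, adj, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("Monte-Carlo cluster p matches the exhaustive sign-flip null", {
  labels5 <- c("F3", "Fz", "F4", "C3", "Cz")
  adj <- build_adjacency(labels5)
  n <- 6
  set.seed(53)
  A <- array(rnorm(n * 5 * 50), c(n, 5, 50))
  B <- array(rnorm(n * 5 * 50), c(n, 5, 50))
  # moderate common shift creates mid-scale clusters
  A[, , 20:30] <- A[, , 20:30] + 1.1
  res <- cluster_permutation_test(A, B, adj, n_perm = 5000, seed = 9,
                                  min_neighbors = 0)
  expect_gt(nrow(res$clusters), 0)

  d <- A - B
  thresh <- qt(0.975, n - 1)
  null_exact <- oracle_exhaustive_null(d, adj$matrix, thresh,
                                       min_neighbors = 0)
  expect_length(null_exact, 64)
  for (k in seq_len(min(3, nrow(res$clusters)))) {
    p_exact <- mean(null_exact >= abs(res$clusters$mass[k]) * (1 - 1e-9))
    expect_lt(abs(res$clusters$p[k] - p_exact), 0.02)
  }
})

test_that("observed cluster statistics are subject-order invariant and
           monotone in effect size", {
  adj <- build_adjacency(c("F3", "Fz", "F4", "C3", "Cz"))
  set.seed(54)
  A <- array(rnorm(10 * 5 * 40), c(10, 5, 40))
  B <- array(rnorm(10 * 5 * 40), c(10, 5, 40))
  A[, 2, 15:25] <- A[, 2, 15:25] + 1.5
  r1 <- cluster_permutation_test(A, B, adj, n_perm = 200, seed = 1)
  perm <- sample(10)
  r2 <- cluster_permutation_test(A[perm, , ], B[perm, , ], adj,
                                 n_perm = 200, seed = 1)
  expect_equal(sort(r1$clusters$mass), sort(r2$clusters$mass))

  # enlarging the injected effect on fixed noise never shrinks the mass
  masses <- vapply(c(1, 1.5, 2.5), function(eff) {
    A2 <- A
    A2[, 2, 15:25] <- A[, 2, 15:25] - 1.5 + eff
    r <- cluster_permutation_test(A2, B, adj, n_perm = 100, seed = 1)
    if (nrow(r$clusters)) max(abs(r$clusters$mass)) else 0
  }, numeric(1))
  expect_true(all(diff(masses) >= 0))
})

test_that("pointwise permutation test is exact in the single-point case", {
  set.seed(55)
  a <- matrix(rnorm(8 * 20), 8)
  res <- pointwise_permutation_test(a, a, n_perm = 200, seed = 1)
  expect_true(all(res$p == 1))

  # one time point, n = 6: compare with exhaustive enumeration
  n <- 6
  x <- matrix(rnorm(n) + 1.2, n, 1)
  y <- matrix(rnorm(n), n, 1)
  res <- pointwise_permutation_test(x, y, n_perm = 5000, seed = 2)
  d <- drop(x - y)
  t_obs <- mean(d) / (sd(d) / sqrt(n))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  t_null <- apply(signs, 1, function(s) {
    ds <- d * s
    mean(ds) / (sd(ds) / sqrt(n))
  })
  p_exact <- mean(abs(t_null) >= abs(t_obs))
  expect_lt(abs(res$p - p_exact), 0.02)
})

test_that("BH-FDR equals the step-up definition", {
  expect_identical(bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05),
                   c(TRUE, TRUE, TRUE, FALSE))
  expect_false(any(bh_fdr(rep(1, 10))))
  expect_true(bh_fdr(0.01, q = 0.05))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")

  set.seed(56)
  for (i in 1:50) {
    p <- runif(sample(5:100, 1))^sample(1:3, 1)
    expect_identical(bh_fdr(p, q = 0.05), oracle_bh(p, 0.05))
  }
})
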
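test_that("cone fitting selects the pure columns of a conic mixture", {
  # columns: e1, e2, and an equal mixture; the pure pair is the only
  # 2-subset that reconstructs everything with non-negative coefficients
  A <- cbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  fm <- cone_fitting(A, c = 2, seed = 0)
  expect_setequal(fm$source_pixels, c(1L, 2L))
  rec <- fm$T %*% fm$S
  expect_lt(max(abs(rec - A)), 1e-10)

  # exhaustive oracle over all 2-subsets
  feasible <- vapply(utils::combn(3, 2, simplify = FALSE), function(sub) {
    errs <- vapply(1:3, function(j)
      tiny_nnls(A[, sub, drop = FALSE], A[, j])$err, numeric(1))
    all(errs < 1e-9)
  }, logical(1))
  expect_equal(which(feasible),
               which(vapply(utils::combn(3, 2, simplify = FALSE),
                            function(s) setequal(s, c(1, 2)), logical(1))))
})

test_that("identical columns collapse after one extreme vector", {
  v <- c(3, 4)
  A <- cbind(v, v, v)
  fm <- cone_fitting(A, c = 1, seed = 0)
  expect_equal(fm$T[, 1], v / 5)
  expect_lt(max(abs(fm$T %*% fm$S - A)), 1e-10)
  expect_lt(fm$residual_fro[2], 1e-10)
})

test_that("pure generators are recovered on constructed conic mixtures", {
  set.seed(31)
  for (q in 2:4) {
    m <- 8L
    G <- matrix(rnorm(m * q), m, q)           # generators, general position
    n_mix <- 8L
    # strictly interior mixtures: convex weights scaled below 1
    W <- matrix(runif(q * n_mix), q, n_mix)
    W <- sweep(W, 2, colSums(W), "/") *
      rep(runif(n_mix, 0.3, 0.95), each = q)
    A <- cbind(G, G %*% W)                    # pure columns first
    perm <- sample(ncol(A))
    A <- A[, perm]
    pure <- match(seq_len(q), perm)
    fm <- cone_fitting(A, c = q, seed = 1)
    expect_setequal(fm$source_pixels, pure)
    # oracle: the pure subset reconstructs every column non-negatively
    errs <- vapply(seq_len(ncol(A)), function(j)
      tiny_nnls(A[, pure, drop = FALSE], A[, j])$err, numeric(1))
    expect_lt(max(errs), 1e-8)
  }
})

test_that("residual norm decreases monotonically and S stays non-negative", {
  set.seed(32)
  for (rep in 1:4) {
    A <- matrix(rnorm(15 * 40), 15, 40)
    fm <- cone_fitting(A, c = 10, seed = rep)
    expect_true(all(diff(fm$residual_fro) <= 1e-9))
    expect_true(all(fm$S >= 0))
    expect_lt(max(abs(colSums(fm$T^2) - 1)), 1e-10)
    expect_equal(anyDuplicated(fm$source_pixels), 0L)
    # downdating drives each chosen column's residual to ~0
    expect_lt(max(fm$selected_residual), 1e-8)
  }
})

test_that("selection is nested in c for a fixed seed", {
  set.seed(33)
  A <- matrix(rnorm(12 * 30), 12, 30)
  m5 <- cone_fitting(A, c = 5, seed = 4)
  m10 <- cone_fitting(A, c = 10, seed = 4)
  expect_true(nested_prefix_check(m5, m10))
  expect_true(nested_prefix_check(m5, m5))
  m10b <- cone_fitting(A, c = 10, seed = 5)
  expect_error(nested_prefix_check(m5, m10b), "different seeds")
})

test_that("selection in full-k PCA space matches the full matrix", {
  set.seed(34)
  A <- matrix(rnorm(18 * 50), 18, 50)
  A <- sweep(A, 2, colMeans(A))
  pc <- pca(A, k = 17)        # centring leaves rank m - 1
  full <- cone_fitting(A, c = 6, seed = 2)
  red <- cone_fitting(pca_scores(pc), c = 6, seed = 2)
  expect_equal(red$source_pixels, full$source_pixels)
})

test_that("degenerate inputs stop early or error cleanly", {
  A <- cbind(c(1, 0), c(2, 0), c(0.5, 0))   # rank 1
  expect_warning(fm <- cone_fitting(A, c = 2, seed = 0), "fewer than c")
  expect_equal(fm$c, 1L)
  expect_error(cone_fitting(A, c = 4, seed = 0), "c must be")
  expect_error(cone_fitting(matrix(0, 2, 3), c = 1), "nonzero")
})

test_that("induced clustering takes the argmax row with stated tie rules", {
  S <- rbind(c(1, 0), c(0, 2))
  expect_equal(as.vector(t(unclass(induced_clustering(S, 1, 2)))), c(1L, 2L))
  S0 <- rbind(c(1, 0), c(0, 0))
  expect_equal(as.vector(t(unclass(induced_clustering(S0, 1, 2)))),
               c(1L, 0L))
  St <- rbind(c(3, 1), c(3, 2))
  expect_equal(as.vector(t(unclass(induced_clustering(St, 1, 2)))),
               c(1L, 2L))
  expect_error(induced_clustering(rbind(c(-1, 0)), 1, 2), "non-negative")
})

test_that("back projection solves the least squares factor recovery", {
  set.seed(35)
  # orthonormal rows: pseudoinverse is the transpose
  S <- qr.Q(qr(matrix(rnorm(6 * 3), 6, 3)))
  S <- t(S)
  A <- matrix(rnorm(10 * 6), 10, 6)
  expect_equal(back_project(A, S), A %*% t(S), tolerance = 1e-10)

  T0 <- matrix(rnorm(10 * 3), 10, 3)
  S2 <- matrix(runif(3 * 6), 3, 6)
  expect_lt(max(abs(back_project(T0 %*% S2, S2) - T0)), 1e-8)

  S1 <- matrix(c(1, 0, 0, 0, 0, 0), 1, 6)
  expect_equal(as.vector(back_project(A, S1)), A[, 1])

  Sdef <- rbind(S2[1, ], S2[1, ])
  expect_error(back_project(A, Sdef), "rank")
})
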
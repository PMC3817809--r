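test_that("zscore centres and scales each pixel by its sample sd", {
  mv <- movie_matrix(cbind(c(1, 2, 3), c(5, 5, 5)), 1, 2)
  z <- zscore(mv)
  expect_equal(z$movie$data[, 1], c(-1, 0, 1))
  expect_equal(z$stats$mu, c(2, 5))
  expect_equal(z$stats$sigma[1], 1)
  # constant column becomes all-zero and is flagged
  expect_equal(z$movie$data[, 2], c(0, 0, 0))
  expect_true(z$stats$zero_variance[2])
  expect_false(z$stats$zero_variance[1])
  expect_error(zscore(movie_matrix(matrix(1, 1, 1), 1, 1)), "2 frames")
})

test_that("zscore output moments match an independent summation oracle", {
  set.seed(42)
  mv <- movie_matrix(matrix(rnorm(50 * 12, mean = 3, sd = 2), 50, 12), 3, 4)
  z <- zscore(mv)$movie$data
  for (j in seq_len(ncol(z))) {
    s1 <- 0; for (v in z[, j]) s1 <- s1 + v            # naive sums
    mean_j <- s1 / nrow(z)
    s2 <- 0; for (v in z[, j]) s2 <- s2 + (v - mean_j)^2
    expect_lt(abs(mean_j), 1e-12)
    expect_lt(abs(sqrt(s2 / (nrow(z) - 1)) - 1), 1e-12)
  }
})

test_that("zscore is idempotent", {
  set.seed(1)
  mv <- movie_matrix(matrix(rnorm(40 * 9), 40, 9), 3, 3)
  z1 <- zscore(mv)$movie
  z2 <- zscore(z1)$movie
  expect_lt(max(abs(z1$data - z2$data)), 1e-10)
})

test_that("fold change subtracts (and optionally divides by) baseline mean", {
  mv <- movie_matrix(matrix(c(10, 10, 14, 12), 4, 1), 1, 1)
  wnd <- stimulus_window(segment = 1, baseline = c(1, 2), onset = 3)
  expect_equal(as.vector(fold_change(mv, wnd)$data), c(0, 0, 4, 2))
  expect_equal(as.vector(fold_change(mv, wnd, divide = TRUE)$data),
               c(0, 0, 0.4, 0.2))
  # degenerate baselines and out-of-segment windows error
  expect_error(stimulus_window(1, c(2, 1), 3), "from <= to")
  expect_error(fold_change(mv, stimulus_window(1, c(1, 2), 9)),
               "past segment")
  # zero baseline with divide errors naming the pixel
  mv0 <- movie_matrix(matrix(c(0, 0, 1, 2), 4, 1), 1, 1)
  expect_error(fold_change(mv0, wnd, divide = TRUE), "pixel")
})

test_that("fold change leaves segments without a window untouched", {
  a <- movie_matrix(matrix(5, 4, 2), 1, 2)
  b <- movie_matrix(matrix(c(1, 2, 3, 4, 1, 2, 3, 4), 4, 2), 1, 2)
  mv <- concat_movies(list(a, b))
  out <- fold_change(mv, stimulus_window(2, c(1, 2), 3))
  expect_equal(out$data[1:4, ], a$data)                   # untouched
  expect_equal(out$data[5:8, 1], c(-0.5, 0.5, 1.5, 2.5))
})

test_that("spatial Gaussian preserves constants and total mass", {
  mv <- movie_matrix(matrix(3.7, 2, 81), 9, 9)
  out <- spatial_gauss(mv, 3)
  expect_lt(max(abs(out$data - 3.7)), 1e-12)

  imp <- matrix(0, 9, 9); imp[5, 5] <- 2.5
  mvi <- movie_matrix(rbind(as.vector(t(imp))), 9, 9)
  outi <- spatial_gauss(mvi, 3)
  expect_equal(sum(outi$data), 2.5, tolerance = 1e-12)
  expect_error(spatial_gauss(mv, 4), "odd")
})

test_that("width-7 Gaussian equals brute-force dense convolution", {
  set.seed(5)
  h <- 11L; w <- 13L
  img <- matrix(rnorm(h * w), h, w)
  mv <- movie_matrix(rbind(as.vector(t(img))), h, w)
  out <- get_frame(spatial_gauss(mv, 7), 1)
  k1 <- exp(-(-3:3)^2 / (2 * (7 / 4)^2)); k1 <- k1 / sum(k1)
  oracle <- dense_conv2(img, outer(k1, k1))
  expect_lt(max(abs(out - oracle)), 1e-10)
})

test_that("spatial Gaussian commutes with frame reordering", {
  set.seed(6)
  mv <- movie_matrix(matrix(rnorm(6 * 25), 6, 25), 5, 5)
  perm <- c(3, 1, 6, 2, 5, 4)
  a <- spatial_gauss(mv, 5)$data[perm, ]
  mv2 <- mv; mv2$data <- mv$data[perm, ]
  b <- spatial_gauss(mv2, 5)$data
  expect_equal(a, b)
})

test_that("temporal filter averages with shrunken edge windows", {
  mv <- movie_matrix(matrix(1:5, 5, 1), 1, 1)
  expect_equal(as.vector(temporal_filter(mv, 3)$data),
               c(1.5, 2, 3, 4, 4.5))
  expect_equal(temporal_filter(mv, 1)$data, mv$data)
  expect_error(temporal_filter(mv, 7), "segment")
})

test_that("temporal filter respects segment boundaries", {
  set.seed(8)
  a <- movie_matrix(matrix(rnorm(10 * 4), 10, 4), 2, 2)
  b <- movie_matrix(matrix(rnorm(7 * 4), 7, 4), 2, 2)
  joint <- temporal_filter(concat_movies(list(a, b)), 5)
  sep <- rbind(temporal_filter(a, 5)$data, temporal_filter(b, 5)$data)
  expect_equal(joint$data, sep)
})

test_that("image arithmetic behaves elementwise with error checks", {
  set.seed(9)
  a <- movie_matrix(matrix(rnorm(12) + 5, 3, 4), 2, 2)
  b <- movie_matrix(matrix(rnorm(12) + 5, 3, 4), 2, 2)
  expect_true(all(image_arithmetic(a, a, "ratio")$data == 1))
  expect_true(all(image_arithmetic(a, a, "subtract")$data == 0))
  back <- image_arithmetic(image_arithmetic(a, b, "add"), b, "subtract")
  expect_lt(max(abs(back$data - a$data)), 1e-12)
  z <- movie_matrix(matrix(0, 3, 4), 2, 2)
  expect_error(image_arithmetic(a, z, "ratio"), "zero")
  small <- movie_matrix(matrix(1, 3, 1), 1, 1)
  expect_error(image_arithmetic(a, small, "add"), "shape")
})

test_that("stabilise recovers a constructed integer shift", {
  set.seed(10)
  h <- 20L; w <- 24L
  base <- matrix(rnorm(h * w), h, w)
  seg1 <- movie_matrix(t(vapply(1:8, function(i)
    as.vector(t(base)) + rnorm(h * w, sd = 0.01), numeric(h * w))), h, w)
  # second segment: same scene displaced down 2, left 1
  shifted <- matrix(0, h, w)
  shifted[3:h, 1:(w - 1)] <- base[1:(h - 2), 2:w]
  shifted[1:2, ] <- base[1:2, ]; shifted[, w] <- base[, w]
  seg2 <- movie_matrix(t(vapply(1:8, function(i)
    as.vector(t(shifted)) + rnorm(h * w, sd = 0.01), numeric(h * w))), h, w)
  mv <- concat_movies(list(seg1, seg2))
  st <- stabilise(mv, radius = 4)
  expect_equal(st$shifts[[1]], c(0L, 0L))
  expect_equal(st$shifts[[2]], c(2L, -1L))
  # aligned mean frames agree on the interior overlap
  m1 <- matrix(colMeans(st$movie$data[1:8, ]), h, w, byrow = TRUE)
  m2 <- matrix(colMeans(st$movie$data[9:16, ]), h, w, byrow = TRUE)
  interior <- cbind(rep(5:(h - 5), each = length(5:(w - 5))),
                    rep(5:(w - 5), times = length(5:(h - 5))))
  expect_lt(max(abs(m1[interior] - m2[interior])), 0.05)
})

test_that("stabilise is a no-op for aligned or single-segment movies", {
  set.seed(11)
  mv <- movie_matrix(matrix(rnorm(5 * 100), 5, 100), 10, 10)
  st <- stabilise(mv)
  expect_equal(st$movie$data, mv$data)
  expect_equal(st$shifts, list(c(0L, 0L)))

  both <- concat_movies(list(mv, mv))
  st2 <- stabilise(both, radius = 3)
  expect_equal(st2$shifts[[2]], c(0L, 0L))
  expect_equal(st2$movie$data, both$data)

  expect_error(stabilise(both, radius = 5), "radius")
})
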
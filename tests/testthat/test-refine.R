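test_that("noise-free disjoint clusters are recovered exactly", {
  spec <- synthetic_spec(cluster_radius = 6, sigma_noise = 0, seed = 13)
  gen <- generate_movie(spec)
  out <- extract_signals(gen$movie, k = 16, c = 16, min_similarity = 0,
                         seed = 0)
  rf <- out$refined
  expect_equal(ncol(rf$T_hat), 16L)
  # members match the generating clusters exactly (up to signal order)
  got <- lapply(rf$members, sort)
  want <- lapply(gen$truth$masks, sort)
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
  # each refined signal is a perfect correlate of one source
  sc <- correlation_score(rf$T_hat, gen$truth$U)
  expect_true(all(sc$per_signal$rho > 1 - 1e-9))
})

test_that("min_similarity = 1 keeps only exact duplicates of basis columns", {
  mv <- tiny_two_source_movie()
  z <- zscore(mv)$movie
  fm <- cone_fitting(z, c = 2, seed = 0)
  rf <- refine(z, fm, min_similarity = 1)
  # pixels 1,2 are duplicates of one basis column, 3,4 of the other;
  # the flat pixel is zero after z-scoring and never assigned
  expect_setequal(lapply(rf$members, sort), list(c(1L, 2L), c(3L, 4L)))
  expect_equal(sort(rf$unassigned), 5L)
})

test_that("overlap pixels are left white at high min_similarity", {
  spec <- synthetic_spec(cluster_radius = 8, sigma_noise = 0, seed = 14)
  gen <- generate_movie(spec)
  expect_gt(length(gen$truth$overlap), 0)
  z <- zscore(gen$movie)$movie
  # basis of known pure pixels (disc centres), isolating the threshold rule
  # from the greedy selection
  px <- pixel_index(round(spec$centres[, 1]) + 1L,
                    round(spec$centres[, 2]) + 1L, spec$width)
  B <- z$data[, px, drop = FALSE]
  fm <- structure(list(T = sweep(B, 2, sqrt(colSums(B^2)), "/"),
                       S = matrix(1, 16, ncol(z$data)),
                       order = 1:16, source_pixels = px, c = 16L,
                       init_seed = 0L),
                  class = "factor_model")
  rf <- refine(z, fm, min_similarity = 0.95)
  # mixtures never reach cosine sqrt((1 + rho) / 2) < 0.95 when rho < 0.5
  expect_true(all(gen$truth$overlap %in% rf$unassigned))
  # pure in-disc pixels duplicate their source exactly and stay assigned
  assigned <- unlist(rf$members)
  pure <- setdiff(unlist(gen$truth$masks), gen$truth$overlap)
  expect_true(all(pure %in% assigned))
})

test_that("refined supports are pairwise disjoint and cover assignments", {
  spec <- synthetic_spec(sigma_noise = 0.5, seed = 15)
  gen <- generate_movie(spec)
  out <- extract_signals(gen$movie, k = 20, c = 20, seed = 0)
  rf <- out$refined
  supports <- apply(rf$S_hat, 1, function(s) which(s != 0),
                    simplify = FALSE)
  expect_equal(sum(lengths(supports)), length(unique(unlist(supports))))
  expect_setequal(unlist(supports), unlist(rf$members))
  # unassigned + members partition all pixels
  expect_setequal(c(unlist(rf$members), rf$unassigned),
                  seq_len(prod(dim(rf$S_hat)[2])))
  expect_error(refine(zscore(gen$movie)$movie, list()), "factor_model")
})

test_that("low-rank reconstruction matches noise-free data on assigned pixels", {
  spec <- synthetic_spec(cluster_radius = 6, sigma_noise = 0, seed = 16)
  gen <- generate_movie(spec)
  out <- extract_signals(gen$movie, k = 16, c = 16, seed = 0)
  # reconstruct in raw units: refine on the raw movie model
  zin <- zscore(gen$movie)$movie
  rec <- low_rank_movie(out$refined)
  assigned <- unlist(out$refined$members)
  err <- norm(rec$data[, assigned] - zin$data[, assigned], "F") /
    norm(zin$data[, assigned], "F")
  expect_lt(err, 1e-6)
  # numerical rank of the reconstruction is at most c
  sv <- svd(rec$data)$d
  expect_lt(sv[17] / sv[1], 1e-10)
})

test_that("rank-1 refined model yields frames proportional to its map", {
  mv <- tiny_two_source_movie()
  z <- zscore(mv)$movie
  fm <- cone_fitting(z, c = 1, seed = 0)
  rf <- refine(z, fm, min_similarity = 0.2)
  rec <- low_rank_movie(rf)
  map_row <- rf$S_hat[1, ]
  for (i in c(1, 5, 20)) {
    expect_equal(rec$data[i, ], rf$T_hat[i, 1] * map_row, tolerance = 1e-10)
  }
})

test_that("models serialise to a directory and load back", {
  spec <- synthetic_spec(cluster_radius = 6, sigma_noise = 0.2, seed = 17,
                         m = 80L, height = 30L, width = 30L, n_sources = 4L)
  gen <- generate_movie(spec)
  out <- extract_signals(gen$movie, k = 4, c = 4, seed = 0)
  d1 <- file.path(tempdir(), "fm_dir")
  save_model(out$model, d1)
  fm2 <- load_model(d1)
  expect_equal(fm2$source_pixels, out$model$source_pixels)
  expect_equal(fm2$T, out$model$T, tolerance = 1e-12)
  expect_equal(fm2$S, out$model$S, tolerance = 1e-12)

  d2 <- file.path(tempdir(), "rf_dir")
  save_model(out$refined, d2)
  rf2 <- load_model(d2)
  expect_equal(rf2$members, out$refined$members)
  expect_equal(rf2$T_hat, out$refined$T_hat, tolerance = 1e-12)
  expect_equal(rf2$height, out$refined$height)
})
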
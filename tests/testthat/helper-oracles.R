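# Independent oracles used across tests. These deliberately use naive
# O(everything) implementations so they share no code with the package.

# Exact tiny non-negative least squares by enumerating active sets:
# minimises ||a - B x|| over x >= 0 for ncol(B) <= ~6.
tiny_nnls <- function(B, a) {
  q <- ncol(B)
  best <- NULL
  best_err <- Inf
  for (bits in 0:(2^q - 1)) {
    free <- which(bitwAnd(bits, 2^(seq_len(q) - 1L)) > 0L)
    x <- numeric(q)
    if (length(free) > 0L) {
      Bf <- B[, free, drop = FALSE]
      sol <- tryCatch(qr.solve(Bf, a), error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (all(x >= -1e-9)) {
      err <- sqrt(sum((a - B %*% pmax(x, 0))^2))
      if (err < best_err) {
        best_err <- err
        best <- pmax(x, 0)
      }
    }
  }
  list(x = best, err = best_err)
}

# Brute-force 2-D convolution of an image with a kernel, symmetric padding.
dense_conv2 <- function(img, kernel) {
  h <- nrow(img); w <- ncol(img)
  kh <- (nrow(kernel) - 1L) %/% 2L
  kw <- (ncol(kernel) - 1L) %/% 2L
  reflect <- function(i, n) {
    if (i < 1L) 1L - i else if (i > n) 2L * n + 1L - i else i
  }
  out <- matrix(0, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      acc <- 0
      for (dr in -kh:kh) {
        for (dc in -kw:kw) {
          sr <- reflect(r + dr, h)
          sc <- reflect(cc + dc, w)
          acc <- acc + img[sr, sc] * kernel[dr + kh + 1L, dc + kw + 1L]
        }
      }
      out[r, cc] <- acc
    }
  }
  out
}

# Largest principal angle (radians) between the row spaces of two matrices.
subspace_angle <- function(A, B) {
  qa <- qr.Q(qr(t(A)))
  qb <- qr.Q(qr(t(B)))
  sv <- svd(crossprod(qa, qb))$d
  acos(min(1, max(-1, min(sv))))
}

# Small deterministic movie: two disjoint 2-pixel clusters with distinct
# signals plus a flat background pixel, on a 1 x 5 strip.
tiny_two_source_movie <- function(m = 40L) {
  t <- seq_len(m)
  u1 <- sin(t / 3)
  u2 <- cos(t / 5) + 0.3 * sin(t / 2)
  data <- cbind(u1, u1, u2, u2, rep(0.5, m))
  dimnames(data) <- NULL
  movie_matrix(data, height = 1L, width = 5L)
}
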
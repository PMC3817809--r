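#' Greedy convex-cone fitting (extreme-vector column selection)
#'
#' Fits the non-negative mixture model `A = T S + N` in which every pixel
#' time series is either a pure source signal or a conic (non-negative)
#' combination of pure sources, as happens where light scatter mixes
#' neighbouring glomeruli. The pure sources are extreme vectors of the
#' convex cone spanned by the data, and this greedy forward heuristic
#' selects, at each of `c` iterations, the column least explained by conic
#' combinations of the columns selected so far:
#'
#' 1. normalise the current residual's chosen column to a unit vector `t`;
#' 2. compute its spatial mapping `s = R' t` on the residual `R` and clip
#'    negative coefficients to zero (`s0`);
#' 3. downdate `R <- R - t s0'`, removing everything `t` explains conically;
#' 4. pick the next column as the residual column of largest Euclidean norm
#'    (ties toward the smallest index).
#'
#' The first column is chosen as the column farthest (Euclidean) from one
#' drawn uniformly at random under `seed` — a hull vector, avoiding a
#' mixed-signal start. Selection is nested: with a fixed seed the first `c1`
#' selections of a `c2 > c1` run coincide with the `c1` run.
#'
#' Typically `A` is the `k x n` PCA-space representation ([pca_scores]), and
#' full-length time courses are recovered afterwards with [back_project].
#'
#' @param A numeric matrix (rows: time or PCA coordinates; columns: pixels),
#'   or a [movie_matrix].
#' @param c number of columns to select, `1 <= c <= n`.
#' @param seed integer seed for the initial draw.
#' @return An object of class `factor_model`: `T` (columns of the *original*
#'   `A` at the selected pixels, unit-normalised), `S` (`c x n`,
#'   non-negative), `order` (selection order, here always `1:c`),
#'   `source_pixels` (1-based pixel index of each selected column), `c`,
#'   `init_seed`, plus diagnostics: `residual_fro` (Frobenius norm of the
#'   residual before selection and after each downdate, nonincreasing) and
#'   `selected_residual` (norm of each chosen column right after its
#'   downdate, ~0).
#' @export
cone_fitting <- function(A, c, seed = 0L) {
  A <- if (inherits(A, "movie_matrix")) A$data else as.matrix(A)
  n <- ncol(A)
  if (c < 1L || c > n) stop("c must be in [1, n]")
  col_norms2 <- colSums(A^2)
  if (all(col_norms2 == 0)) stop("A has no nonzero column")

  j0 <- local_seed(seed, sample.int(n, 1L))
  d2 <- colSums((A - A[, j0])^2)
  p <- which.max(d2)                       # ties break to smallest index

  R <- A
  Tsel <- matrix(0, nrow(A), 0L)
  S <- matrix(0, 0L, n)
  pixels <- integer(0L)
  res_fro <- sqrt(sum(R^2))          # Frobenius norm after each downdate
  sel_res <- numeric(0L)             # residual norm of each selected column
  for (r in seq_len(c)) {
    t_res <- R[, p]
    nrm <- sqrt(sum(t_res^2))
    if (nrm <= 1e-12 * sqrt(max(col_norms2))) {
      warning("residual numerically zero after ", r - 1L,
              " selections; returning fewer than c = ", c)
      break
    }
    t_res <- t_res / nrm
    s <- as.vector(crossprod(R, t_res))
    s0 <- pmax(s, 0)
    R <- R - tcrossprod(t_res, s0)
    pixels <- c(pixels, p)
    orig <- A[, p]
    Tsel <- cbind(Tsel, orig / sqrt(sum(orig^2)))
    S <- rbind(S, s0)
    res_fro <- c(res_fro, sqrt(sum(R^2)))
    sel_res <- c(sel_res, sqrt(sum(R[, p]^2)))
    p <- which.max(colSums(R^2))
  }
  dimnames(S) <- NULL
  structure(list(T = Tsel, S = S, order = seq_along(pixels),
                 source_pixels = pixels, c = length(pixels),
                 init_seed = as.integer(seed),
                 residual_fro = res_fro, selected_residual = sel_res),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model> c = ", x$c, " basis signals over ", ncol(x$S),
      " pixels (seed ", x$init_seed, ")\n", sep = "")
  invisible(x)
}

#' Check the nested-basis prefix property between two fits
#'
#' Cone fitting is nested: given one starting point, the r-th basis vector
#' does not depend on how many further vectors are requested. For two fits
#' of the same matrix with the same seed and `c1 <= c2`, the first `c1`
#' selected pixels (and their order) must coincide.
#'
#' @param model_c1,model_c2 `factor_model` fits with `model_c1$c <=
#'   model_c2$c`, same matrix and seed.
#' @return `TRUE` or `FALSE`.
#' @export
nested_prefix_check <- function(model_c1, model_c2) {
  if (model_c1$init_seed != model_c2$init_seed)
    stop("models were fitted with different seeds")
  c1 <- model_c1$c
  if (c1 > model_c2$c) stop("model_c1 must have the smaller c")
  identical(model_c1$source_pixels, model_c2$source_pixels[seq_len(c1)]) &&
    identical(model_c1$order, model_c2$order[seq_len(c1)])
}

#' Clustering induced by a spatial coefficient matrix
#'
#' Assigns each pixel the (1-based) row index of `S` in which it has its
#' highest coefficient; pixels whose column of `S` is entirely zero get
#' label 0 (unassigned), and ties break toward the smallest row.
#'
#' @param S non-negative `c x n` matrix.
#' @param height,width image geometry with `height * width == n`.
#' @return A [label_map].
#' @export
induced_clustering <- function(S, height, width) {
  S <- as.matrix(S)
  if (any(S < 0)) stop("S must be non-negative")
  if (height * width != ncol(S)) stop("geometry does not match ncol(S)")
  lab <- apply(S, 2L, which.max)           # ties -> smallest index
  lab[colSums(S > 0) == 0L] <- 0L
  label_map(matrix(as.integer(lab), height, width, byrow = TRUE))
}

#' Recover full-length time series for spatial maps by projection
#'
#' Given spatial maps `S` computed in a reduced space, solves the least
#' squares problem `min ||A - T S||_F` for `T = A S+`, giving the
#' full-length time series that correspond to each map row.
#'
#' @param A_full a [movie_matrix] or `m x n` matrix.
#' @param S `c x n` matrix of full row rank.
#' @return `m x c` matrix of time series.
#' @export
back_project <- function(A_full, S) {
  A <- if (inherits(A_full, "movie_matrix")) A_full$data else as.matrix(A_full)
  S <- as.matrix(S)
  if (ncol(A) != ncol(S)) stop("A and S disagree on pixel count")
  G <- tcrossprod(S)
  qrG <- qr(G)
  if (qrG$rank < nrow(S)) stop("S is rank-deficient; cannot back-project")
  t(solve(G, S %*% t(A)))
}
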
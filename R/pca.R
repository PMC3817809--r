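#' Iterative PCA of a movie matrix
#'
#' Computes the top-`k` principal components of an `m x n` movie by NIPALS
#' iteration with deflation. Each component is found by the alternating
#' update `p = X't / t't`, `t = Xp / p'p` until the time course `t`
#' stabilises, then `X` is deflated by the rank-1 term `t p'`. Because both
#' half-steps compose to a power iteration on `X X'`, the iteration is
#' carried in the `min(m, n)`-sized Gram matrix, which changes nothing about
#' the fixed point but makes the per-iteration cost independent of the larger
#' dimension. Successive components are re-orthogonalised against earlier
#' ones each sweep for numerical stability.
#'
#' The caller is responsible for centring (normally [zscore]); `pca` does not
#' centre.
#'
#' With `sampling_fraction < 1`, components are first estimated on a
#' uniformly sampled pixel subset (without replacement, seeded), then
#' extended to all pixels by projecting the movie onto the estimated time
#' courses and re-orthonormalising; this trades a small approximation error
#' for a large speedup on wide movies. `sampling_fraction = 1` takes the
#' exact path and draws no random numbers.
#'
#' If the residual becomes numerically zero before `k` components are found
#' (an exactly low-rank movie), the components found so far are returned
#' with a warning.
#'
#' @param movie a [movie_matrix] or bare numeric matrix (frames by pixels).
#' @param k number of components, `1 <= k <= min(m, n)`.
#' @param sampling_fraction fraction of pixels used to estimate the
#'   components, in `(0, 1]`.
#' @param seed integer seed for the pixel sample (ignored when
#'   `sampling_fraction == 1`).
#' @param tol relative convergence tolerance on the time-course direction.
#' @param max_iter iteration cap per component; exceeding it is an error
#'   reporting the tolerance achieved.
#' @return An object of class `pca_model`: list with `components` (`k x n`,
#'   orthonormal rows), `loadings` (`m x k`; column `r` has squared norm
#'   `eigenvalues[r] * (m - 1)`), `eigenvalues` (nonincreasing), `k`.
#' @export
pca <- function(movie, k, sampling_fraction = 1, seed = 0L,
                tol = 1e-11, max_iter = 100000L) {
  A <- if (inherits(movie, "movie_matrix")) movie$data else as.matrix(movie)
  m <- nrow(A); n <- ncol(A)
  if (k < 1L || k > min(m, n)) stop("k must be in [1, min(m, n)]")
  if (sampling_fraction <= 0 || sampling_fraction > 1)
    stop("sampling_fraction must be in (0, 1]")

  if (sampling_fraction < 1) {
    ns <- max(k, ceiling(sampling_fraction * n))
    idx <- local_seed(seed, sort(sample.int(n, ns)))
    sub <- nipals_gram(A[, idx, drop = FALSE], k, tol, max_iter)
    U <- sub$U   # m x k' orthonormal time courses from the subset
    M <- crossprod(U, A)                    # k' x n projection
    sv <- svd(M)                            # re-orthonormalise over all pixels
    components <- t(sv$v)                   # k' x n, orthonormal rows
    loadings <- (U %*% sv$u) %*% diag(sv$d, nrow = length(sv$d))
    eig <- sv$d^2 / (m - 1)
  } else {
    sub <- nipals_gram(A, k, tol, max_iter)
    loadings <- sub$U %*% diag(sub$d, nrow = length(sub$d))
    components <- t(sub$V)
    eig <- sub$d^2 / (m - 1)
  }
  structure(list(components = components, loadings = loadings,
                 eigenvalues = eig, k = nrow(components)),
            class = "pca_model")
}

## NIPALS with deflation, run on the smaller Gram matrix.
## Returns U (m x k orthonormal), d (singular values), V (n x k orthonormal).
nipals_gram <- function(A, k, tol, max_iter) {
  m <- nrow(A); n <- ncol(A)
  wide <- n >= m
  G <- if (wide) tcrossprod(A) else crossprod(A)   # q x q, q = min(m, n)
  q <- nrow(G)
  total <- sum(diag(G))
  U <- matrix(0, q, 0L)
  d2 <- numeric(0L)
  for (r in seq_len(k)) {
    if (sum(diag(G)) <= max(1e-12 * total, 1e-300)) {
      warning("residual numerically zero after ", r - 1L,
              " components; returning fewer than k = ", k)
      break
    }
    dg <- diag(G)
    t_vec <- G[, which.max(dg)]
    t_vec <- t_vec / sqrt(sum(t_vec^2))
    achieved <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      t_new <- G %*% t_vec
      if (ncol(U) > 0L) t_new <- t_new - U %*% crossprod(U, t_new)
      nrm <- sqrt(sum(t_new^2))
      if (nrm <= 0) { converged <- TRUE; break }  # direction annihilated
      t_new <- as.vector(t_new) / nrm
      achieved <- min(sqrt(sum((t_new - t_vec)^2)),
                      sqrt(sum((t_new + t_vec)^2)))
      t_vec <- t_new
      if (achieved < tol) { converged <- TRUE; break }
    }
    if (!converged)
      stop("NIPALS did not converge for component ", r, " after ", max_iter,
           " iterations (achieved tolerance ", signif(achieved, 3), ")")
    lam <- as.vector(crossprod(t_vec, G %*% t_vec))
    if (lam <= 0) {
      warning("residual numerically zero after ", r - 1L,
              " components; returning fewer than k = ", k)
      break
    }
    U <- cbind(U, t_vec)
    d2 <- c(d2, lam)
    G <- G - lam * tcrossprod(t_vec)
    G <- (G + t(G)) / 2
  }
  if (ncol(U) == 0L) stop("matrix is numerically zero; no components")
  ord <- order(d2, decreasing = TRUE)
  U <- U[, ord, drop = FALSE]
  d2 <- d2[ord]
  d <- sqrt(d2)
  if (wide) {
    V <- crossprod(A, U) %*% diag(1 / d, nrow = length(d))
    list(U = U, d = d, V = V)
  } else {
    Uf <- A %*% U %*% diag(1 / d, nrow = length(d))
    list(U = Uf, d = d, V = U)
  }
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> k = ", x$k, ", n = ", ncol(x$components),
      " pixels; top eigenvalues: ",
      paste(signif(utils::head(x$eigenvalues, 5L), 4), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Pixel representation in PCA space
#'
#' Returns the `k x n` matrix whose column `j` holds pixel `j`'s coordinates
#' in the top-`k` component basis (`diag(d) %*% components`). Euclidean
#' geometry between pixel columns is preserved up to the truncation, which
#' is what lets the cone-fitting selection run on this small matrix instead
#' of the full movie.
#'
#' @param model a `pca_model`.
#' @export
pca_scores <- function(model) {
  d <- sqrt(model$eigenvalues * (nrow(model$loadings) - 1))
  diag(d, nrow = length(d)) %*% model$components
}

## evaluate expr with a temporary RNG state seeded by `seed`
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
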
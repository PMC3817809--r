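#' Signal refinement: average out residual noise, discard mixed pixels
#'
#' The selected basis signals are single noisy pixel time series. Refinement
#' replaces each by the average of all pixels whose time series is closer to
#' it than to any other basis signal — provided that similarity also exceeds
#' `min_similarity`; pixels failing the threshold carry signal mixtures (or
#' pure noise) that are not close enough to any pure source and are left
#' unassigned ("white" in the glomerular map) rather than unmixed.
#'
#' Closeness is cosine similarity between the full-length pixel time series
#' and the full-length unit-normalised basis signal (the movie column at
#' each selected source pixel). The refined signal `T_hat[, r]` is the plain
#' mean of the member pixels' raw time series; row `r` of `S_hat` holds, for
#' each member pixel, its least-squares coefficient on `T_hat[, r]` and is
#' zero elsewhere, so row supports are pairwise disjoint. Basis signals that
#' attract no members are dropped.
#'
#' @param A_full a [movie_matrix] (the same full-length movie, typically
#'   z-scored, from whose reduction `model` was fitted).
#' @param model a `factor_model` from [cone_fitting].
#' @param min_similarity cosine threshold in `[0, 1]`; a pixel is assigned
#'   only if its best similarity is `>=` this value. Default 0.5.
#' @param assign_metric similarity metric; only `"cosine"` is defined.
#' @return An object of class `refined_model`: `T_hat` (`m x c'`), `S_hat`
#'   (`c' x n`, disjoint supports), `members` (list of member pixel indices
#'   per retained signal), `unassigned` (pixel indices), `kept` (indices
#'   into the original `1..c` basis), `height`, `width`, `min_similarity`.
#' @export
refine <- function(A_full, model, min_similarity = 0.5,
                   assign_metric = "cosine") {
  assign_metric <- match.arg(assign_metric, "cosine")
  if (!inherits(model, "factor_model") || model$c < 1L)
    stop("model must be a non-empty factor_model")
  if (min_similarity < 0 || min_similarity > 1)
    stop("min_similarity must be in [0, 1]")
  A <- if (inherits(A_full, "movie_matrix")) A_full$data else as.matrix(A_full)
  h <- if (inherits(A_full, "movie_matrix")) A_full$height else NA_integer_
  w <- if (inherits(A_full, "movie_matrix")) A_full$width else NA_integer_
  n <- ncol(A)
  if (any(model$source_pixels > n)) stop("model does not match this movie")

  B <- A[, model$source_pixels, drop = FALSE]      # full-length basis signals
  bn <- sqrt(colSums(B^2))
  if (any(bn == 0)) stop("a selected basis column is all-zero in A_full")
  B <- sweep(B, 2L, bn, "/")
  pn <- sqrt(colSums(A^2))
  sim <- crossprod(B, A)                           # c x n
  nz <- pn > 0
  sim[, nz] <- sweep(sim[, nz, drop = FALSE], 2L, pn[nz], "/")
  sim[, !nz] <- -Inf                               # zero pixels never assigned

  sim <- pmin(sim, 1)                              # guard rounding above 1
  best <- apply(sim, 2L, which.max)                # ties -> smallest r
  best_sim <- sim[cbind(best, seq_len(n))]
  # small tolerance so exact duplicates (cosine 1 up to rounding) survive
  # a threshold of exactly 1
  assigned <- is.finite(best_sim) & best_sim >= min_similarity - 1e-12

  members <- lapply(seq_len(model$c), function(r) which(assigned & best == r))
  kept <- which(lengths(members) > 0L)
  if (length(kept) == 0L)
    stop("no pixel reached min_similarity = ", min_similarity,
         " for any basis signal")
  members <- members[kept]
  T_hat <- vapply(members, function(px)
    rowMeans(A[, px, drop = FALSE]), numeric(nrow(A)))
  S_hat <- matrix(0, length(kept), n)
  for (r in seq_along(members)) {
    px <- members[[r]]
    th <- T_hat[, r]
    S_hat[r, px] <- as.vector(crossprod(A[, px, drop = FALSE], th)) / sum(th^2)
  }
  unassigned <- which(!assigned)
  structure(list(T_hat = T_hat, S_hat = S_hat, members = members,
                 unassigned = unassigned, kept = kept,
                 height = h, width = w, min_similarity = min_similarity),
            class = "refined_model")
}

#' @export
print.refined_model <- function(x, ...) {
  cat("<refined_model> ", ncol(x$T_hat), " refined signals, ",
      length(x$unassigned), " unassigned pixel(s), min_similarity = ",
      x$min_similarity, "\n", sep = "")
  invisible(x)
}

#' Denoised low-rank reconstruction of a movie
#'
#' Rebuilds the movie as `A_c = T_hat %*% S_hat`: every assigned pixel is
#' replaced by its cluster's refined mean signal scaled by the pixel's
#' coefficient, and unassigned pixels are zero. The result has rank at most
#' the number of refined signals.
#'
#' @param refined a `refined_model` (with geometry, i.e. produced from a
#'   [movie_matrix]).
#' @return A [movie_matrix].
#' @export
low_rank_movie <- function(refined) {
  if (ncol(refined$T_hat) < 1L) stop("refined model is empty")
  if (is.na(refined$height)) stop("refined model lacks image geometry")
  movie_matrix(refined$T_hat %*% refined$S_hat,
               height = refined$height, width = refined$width)
}

#' Glomerular map of a refined model
#'
#' The induced clustering of `S_hat`: each pixel labelled by the refined
#' signal it contributes to, 0 (white) where unassigned.
#'
#' @param refined a `refined_model`.
#' @return A [label_map].
#' @export
refined_label_map <- function(refined) {
  induced_clustering(pmax(refined$S_hat, 0), refined$height, refined$width)
}

#' Serialise / load a fitted model directory
#'
#' Writes `T.csv`, `S.csv`, `members.csv` (pixel, signal) and `meta.json`
#' (class, dimensions, seed, threshold) into `dir`. `load_model` restores
#' the object.
#'
#' @param model a `factor_model` or `refined_model`.
#' @param dir directory to create/fill.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(model, "factor_model")) {
    write_timeseries(model$T, file.path(dir, "T.csv"))
    write_timeseries(t(model$S), file.path(dir, "S.csv"))
    meta <- list(class = "factor_model", c = model$c,
                 source_pixels = model$source_pixels, order = model$order,
                 init_seed = model$init_seed)
  } else if (inherits(model, "refined_model")) {
    write_timeseries(model$T_hat, file.path(dir, "T.csv"))
    write_timeseries(t(model$S_hat), file.path(dir, "S.csv"))
    mem <- data.frame(
      pixel = unlist(model$members),
      signal = rep(seq_along(model$members), lengths(model$members)))
    utils::write.csv(mem, file.path(dir, "members.csv"), row.names = FALSE)
    meta <- list(class = "refined_model", kept = model$kept,
                 unassigned = model$unassigned, height = model$height,
                 width = model$width, min_similarity = model$min_similarity)
  } else stop("unsupported model class")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  T <- read_timeseries(file.path(dir, "T.csv"))
  S <- t(read_timeseries(file.path(dir, "S.csv")))
  dimnames(T) <- dimnames(S) <- NULL
  if (meta$class == "factor_model") {
    structure(list(T = T, S = S, order = as.integer(meta$order),
                   source_pixels = as.integer(meta$source_pixels),
                   c = as.integer(meta$c),
                   init_seed = as.integer(meta$init_seed)),
              class = "factor_model")
  } else {
    mem <- utils::read.csv(file.path(dir, "members.csv"))
    members <- split(mem$pixel, mem$signal)
    names(members) <- NULL
    structure(list(T_hat = T, S_hat = S, members = members,
                   unassigned = as.integer(meta$unassigned),
                   kept = as.integer(meta$kept),
                   height = as.integer(meta$height),
                   width = as.integer(meta$width),
                   min_similarity = meta$min_similarity),
              class = "refined_model")
  }
}
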
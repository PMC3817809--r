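#' Source-recovery correlation score
#'
#' For each recovered signal, the best Pearson correlation against any
#' implanted ground-truth source is found; the score is the mean of these
#' best correlations over the recovered signals (so it lives in `[-1, 1]`,
#' with 1 meaning every recovered signal matches some source perfectly).
#' Matching is many-to-one: a source may be the best match of several
#' recovered signals. Set `one_to_one = TRUE` for a diagnostic greedy
#' one-to-one assignment variant.
#'
#' @param T_hat `m x c'` matrix of recovered signals (e.g. `$T_hat` of a
#'   `refined_model`).
#' @param U `m x q` matrix of ground-truth sources.
#' @param one_to_one use a greedy one-to-one match instead of the default
#'   many-to-one best match.
#' @return An object of class `recovery_result`: `corr` (the score),
#'   `per_signal` (data.frame `signal`, `best_source`, `rho`),
#'   `n_recovered`.
#' @export
correlation_score <- function(T_hat, U, one_to_one = FALSE) {
  T_hat <- as.matrix(T_hat); U <- as.matrix(U)
  if (nrow(T_hat) != nrow(U)) stop("T_hat and U must have the same m")
  if (ncol(T_hat) < 1L || ncol(U) < 1L) stop("need at least one signal each")
  sd_t <- apply(T_hat, 2L, stats::sd)
  if (any(sd_t == 0))
    stop("recovered signal ", which(sd_t == 0)[1L],
         " has zero variance; correlation undefined")
  sd_u <- apply(U, 2L, stats::sd)
  if (any(sd_u == 0))
    stop("source signal ", which(sd_u == 0)[1L],
         " has zero variance; correlation undefined")
  R <- stats::cor(T_hat, U)                      # c' x q
  if (one_to_one) {
    per <- greedy_match(R)
  } else {
    best <- apply(R, 1L, which.max)
    per <- data.frame(signal = seq_len(nrow(R)), best_source = best,
                      rho = R[cbind(seq_len(nrow(R)), best)])
  }
  structure(list(corr = mean(per$rho), per_signal = per,
                 n_recovered = nrow(R)),
            class = "recovery_result")
}

greedy_match <- function(R) {
  per <- data.frame(signal = integer(0), best_source = integer(0),
                    rho = numeric(0))
  Rw <- R
  for (step in seq_len(min(dim(R)))) {
    ij <- arrayInd(which.max(Rw), dim(Rw))
    per <- rbind(per, data.frame(signal = ij[1L], best_source = ij[2L],
                                 rho = R[ij[1L], ij[2L]]))
    Rw[ij[1L], ] <- -Inf
    Rw[, ij[2L]] <- -Inf
  }
  per[order(per$signal), ]
}

#' @export
print.recovery_result <- function(x, ...) {
  cat("<recovery_result> corr = ", signif(x$corr, 4), " over ",
      x$n_recovered, " recovered signal(s)\n", sep = "")
  invisible(x)
}

#' Run the full extraction pipeline on one movie
#'
#' Convenience wrapper chaining optional spatial smoothing, z-score
#' normalisation, PCA reduction, cone fitting on the PCA scores, and signal
#' refinement on the z-scored movie.
#'
#' @param movie a [movie_matrix].
#' @param k principal components (default 50).
#' @param c basis signals to select (default 50).
#' @param filter_width odd Gaussian width, or `NULL` for no smoothing.
#' @param min_similarity refinement threshold, see [refine].
#' @param seed seed for the cone-fitting initialisation.
#' @return list with `refined` (`refined_model`), `model` (`factor_model`),
#'   `pca` (`pca_model`), `zscored` ([movie_matrix]).
#' @export
extract_signals <- function(movie, k = 50L, c = 50L, filter_width = NULL,
                            min_similarity = 0.5, seed = 0L) {
  if (!is.null(filter_width)) movie <- spatial_gauss(movie, filter_width)
  z <- zscore(movie)$movie
  pc <- pca(z, k = k)
  fm <- cone_fitting(pca_scores(pc), c = c, seed = seed)
  rf <- refine(z, fm, min_similarity = min_similarity)
  list(refined = rf, model = fm, pca = pc, zscored = z)
}

#' Noise-sweep benchmark on synthetic movies
#'
#' Re-runs the recovery experiment over a grid of noise levels: for each
#' `sigma` and repetition, a fresh synthetic movie is generated, the full
#' pipeline is run (optionally with spatial Gaussian smoothing), and the
#' recovered refined signals are scored against the implanted sources with
#' [correlation_score].
#'
#' @param base_spec a [synthetic_spec]; its `sigma_noise` and `seed` are
#'   overridden per cell.
#' @param sigmas noise levels to test.
#' @param filter_width odd Gaussian width applied before extraction, or
#'   `NULL` for none. A vector like `list(NULL, 7)` is not accepted; call
#'   twice and rbind to compare.
#' @param k,c,min_similarity,seed pipeline parameters (see
#'   [extract_signals]); `seed` offsets the per-rep generator seeds.
#' @param reps repetitions per noise level.
#' @return data.frame with one row per (sigma, rep): `sigma`, `filtered`,
#'   `rep`, `corr`, `n_recovered`.
#' @export
noise_sweep <- function(base_spec, sigmas, filter_width = NULL, k = 50L,
                        c = 50L, min_similarity = 0.5, reps = 5L,
                        seed = 1L) {
  stopifnot(length(sigmas) >= 1L, reps >= 1L)
  rows <- list()
  for (si in seq_along(sigmas)) {
    for (rep in seq_len(reps)) {
      res <- tryCatch({
        spec <- base_spec
        spec$sigma_noise <- sigmas[si]
        spec$seed <- as.integer(seed + 1000L * si + rep)
        gen <- generate_movie(spec)
        out <- extract_signals(gen$movie, k = k, c = c,
                               filter_width = filter_width,
                               min_similarity = min_similarity, seed = seed)
        sc <- correlation_score(out$refined$T_hat, gen$truth$U)
        data.frame(sigma = sigmas[si],
                   filtered = !is.null(filter_width), rep = rep,
                   corr = sc$corr, n_recovered = sc$n_recovered)
      }, error = function(e) {
        stop("noise_sweep failed at sigma = ", sigmas[si], ", rep = ", rep,
             ": ", conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarise a noise sweep
#' @param sweep data.frame from [noise_sweep] (several can be rbind-ed).
#' @return data.frame with mean `corr` and mean `n_recovered` per
#'   (sigma, filtered) cell.
#' @export
summarise_sweep <- function(sweep) {
  agg <- stats::aggregate(cbind(corr, n_recovered) ~ sigma + filtered,
                          data = sweep, FUN = mean)
  agg[order(agg$filtered, agg$sigma), ]
}

#' Plot a noise sweep
#'
#' Mean correlation score against noise level, one line per filtering
#' condition.
#'
#' @param sweep data.frame from [noise_sweep].
#' @return a ggplot object.
#' @export
plot_noise_sweep <- function(sweep) {
  agg <- summarise_sweep(sweep)
  agg$filtering <- ifelse(agg$filtered, "spatially filtered", "unfiltered")
  ggplot2::ggplot(agg, ggplot2::aes(x = sigma, y = corr,
                                    colour = filtering)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(sigma ~ "(noise sd)"),
                  y = "mean correlation score", colour = NULL) +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
}

#' Display a label map
#'
#' Base-graphics image of a glomerular map; unassigned (label 0) pixels are
#' white, clusters get distinct colours.
#'
#' @param map a [label_map].
#' @param ... passed to [graphics::image].
#' @export
plot_label_map <- function(map, ...) {
  lab <- unclass(map)
  cmax <- max(lab)
  cols <- c("white", grDevices::hcl.colors(max(cmax, 1L), "Spectral"))
  graphics::image(t(lab)[, rev(seq_len(nrow(lab))), drop = FALSE],
                  col = cols[sort(unique(as.vector(lab))) + 1L],
                  axes = FALSE, asp = nrow(lab) / ncol(lab), ...)
  invisible(map)
}
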
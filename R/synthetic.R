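#' Specification of a synthetic antennal-lobe movie
#'
#' Describes an artificial imaging movie with known ground truth: 16 source
#' signals assigned to circular, spatially contiguous and (by default)
#' partially overlapping pixel clusters on a grid, additive mixing where
#' clusters overlap, and i.i.d. Gaussian pixel noise on top. Two source
#' kinds are emulated: `"odours"` (stimulus-locked response transients with
#' high peak amplitudes) and `"idle"` (lower-amplitude spontaneous
#' background activity).
#'
#' Defaults: 16 sources on a 4 x 4 grid of discs of radius 8 px with centre
#' spacing 14 px on a 60 x 60 image, so adjacent discs overlap (about 15% of
#' in-disc pixels lie in an overlap) while each disc centre remains pure;
#' 400 frames. With `cluster_radius <=` half the spacing (e.g. 6) the discs
#' are disjoint, which the exactness tests use.
#'
#' @param n_sources number of ground-truth sources (a square number; the
#'   grid is `sqrt(n) x sqrt(n)`). Default 16.
#' @param m frames. Default 400.
#' @param height,width image size. Default 60 x 60.
#' @param cluster_radius disc radius in px. Default 8 (overlapping).
#' @param sigma_noise standard deviation of the added Gaussian noise, in
#'   units of the (unit-variance) source signals. Default 0.
#' @param source_kind `"odours"` or `"idle"`.
#' @param seed integer master seed; all randomness (sources, then noise)
#'   derives from it through fixed substreams.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sources = 16L, m = 400L, height = 60L,
                           width = 60L, cluster_radius = 8,
                           sigma_noise = 0, source_kind = c("odours", "idle"),
                           seed = 1L) {
  source_kind <- match.arg(source_kind)
  side <- sqrt(n_sources)
  if (side != round(side) || n_sources < 2L)
    stop("n_sources must be a square number >= 4")
  if (sigma_noise < 0) stop("sigma_noise must be >= 0")
  centres <- cluster_centres(as.integer(side), height, width)
  if (any(centres[, 1L] - cluster_radius < 0) ||
      any(centres[, 1L] + cluster_radius > height - 1) ||
      any(centres[, 2L] - cluster_radius < 0) ||
      any(centres[, 2L] + cluster_radius > width - 1))
    stop("clusters do not fit inside the image; reduce cluster_radius")
  structure(list(n_sources = as.integer(n_sources), m = as.integer(m),
                 height = as.integer(height), width = as.integer(width),
                 cluster_radius = cluster_radius, centres = centres,
                 sigma_noise = sigma_noise, source_kind = source_kind,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## grid of disc centres (0-based continuous coordinates), spacing 14 px for
## the default 60 x 60 / 4 x 4 layout, centred in the image
cluster_centres <- function(side, height, width) {
  spacing_r <- (height - 18) / max(side - 1L, 1L)
  spacing_c <- (width - 18) / max(side - 1L, 1L)
  rows <- 9 + spacing_r * (seq_len(side) - 1L)
  cols <- 9 + spacing_c * (seq_len(side) - 1L)
  as.matrix(expand.grid(row = rows, col = cols))[, c(1L, 2L)]
}

## onset frames of the shared stimulus schedule
stimulus_onsets <- function(m) {
  ns <- max(2L, min(8L, m %/% 50L))
  round(seq(from = m * 0.1, by = m * 0.88 / ns, length.out = ns))
}

## double-exponential response transient starting at t0 (frames, 1-based)
transient <- function(m, t0, tau_rise, tau_decay) {
  t <- seq_len(m) - t0
  out <- numeric(m)
  pos <- t >= 0
  out[pos] <- exp(-t[pos] / tau_decay) - exp(-t[pos] / tau_rise)
  out
}

ar1 <- function(m, phi, innov_sd) {
  as.vector(stats::filter(stats::rnorm(m, sd = innov_sd), phi,
                          method = "recursive"))
}

#' Generate ground-truth source signals
#'
#' For `"odours"` sources, each signal is a sum of stimulus-locked
#' double-exponential transients on a shared onset schedule — each source
#' responds to a random subset of the stimuli (at least one) with
#' per-transient amplitude drawn from `[0.5, 1.5]` and a per-source decay
#' constant from `[5, 20]` frames — plus a small AR(1) background. For
#' `"idle"` sources, the signal is smoothed AR(1) background only. Each
#' column is then standardised to mean 0, sd 1 and shifted by its minimum to
#' be non-negative. Sources are distinct but not uncorrelated; pairwise
#' Pearson `|rho| < 0.5` is enforced by rejection (regenerating an
#' offending source, up to 200 tries).
#'
#' @param spec a [synthetic_spec].
#' @return `m x n_sources` matrix `U`; attribute `"onsets"` carries the
#'   stimulus onset frames (also for `"idle"`, where they are unused).
#' @export
generate_sources <- function(spec) {
  local_seed(spec$seed, generate_sources_impl(spec))
}

generate_sources_impl <- function(spec) {
  m <- spec$m
  onsets <- stimulus_onsets(m)
  draw <- function() {
    if (spec$source_kind == "odours") {
      tau_d <- stats::runif(1L, 5, 20)
      resp <- stats::runif(length(onsets)) < 0.45
      if (!any(resp)) resp[sample.int(length(onsets), 1L)] <- TRUE
      amp <- stats::runif(length(onsets), 0.5, 1.5)
      sig <- numeric(m)
      for (s in which(resp))
        sig <- sig + amp[s] * transient(m, onsets[s], tau_rise = 2,
                                        tau_decay = tau_d)
      sig + ar1(m, phi = 0.9, innov_sd = 0.06)
    } else {
      raw <- ar1(m, phi = 0.95, innov_sd = 1)
      as.vector(stats::filter(raw, rep(1 / 5, 5), sides = 2L,
                              circular = TRUE))
    }
  }
  U <- matrix(0, m, spec$n_sources)
  for (j in seq_len(spec$n_sources)) {
    ok <- FALSE
    for (try in seq_len(200L)) {
      u <- draw()
      u <- (u - mean(u)) / stats::sd(u)
      if (j == 1L || all(abs(stats::cor(u, U[, seq_len(j - 1L),
                                             drop = FALSE])) < 0.5)) {
        U[, j] <- u
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("could not draw source ", j, " with pairwise |rho| < 0.5 after ",
           "200 tries; increase m (more frames decorrelate sources)")
  }
  U <- sweep(U, 2L, apply(U, 2L, min), "-")   # shift to be non-negative
  attr(U, "onsets") <- onsets
  U
}

#' Generate a synthetic movie with ground truth
#'
#' Pixel `p`'s time series is the sum of the source signals of every cluster
#' disc containing `p` (additive mixing in overlaps), plus i.i.d.
#' `N(0, sigma_noise^2)` noise. All randomness flows from `spec$seed`:
#' substream `seed` drives the sources, substream `seed + 500009` the noise
#' field, so the same spec always yields a bit-identical movie.
#'
#' @param spec a [synthetic_spec].
#' @return list with `movie` (a [movie_matrix]) and `truth`, an object of
#'   class `synthetic_truth`: `U` (`m x n_sources`), `masks` (list of pixel
#'   index vectors), `overlap` (pixels in more than one mask), `noise`
#'   (the realised `m x n` noise matrix), `onsets`, `spec`.
#' @export
generate_movie <- function(spec) {
  U <- generate_sources(spec)
  h <- spec$height; w <- spec$width; n <- h * w
  coords <- pixel_coords(seq_len(n), w)    # 1-based (row, col)
  masks <- lapply(seq_len(spec$n_sources), function(j) {
    cy <- spec$centres[j, 1L]; cx <- spec$centres[j, 2L]
    which((coords[, 1L] - 1 - cy)^2 + (coords[, 2L] - 1 - cx)^2 <=
            spec$cluster_radius^2)
  })
  M <- matrix(0, spec$n_sources, n)        # membership indicator
  for (j in seq_len(spec$n_sources)) M[j, masks[[j]]] <- 1
  clean <- U %*% M
  noise <- local_seed(spec$seed + 500009L,
                      matrix(stats::rnorm(spec$m * n, sd = spec$sigma_noise),
                             spec$m, n))
  movie <- movie_matrix(clean + noise, height = h, width = w)
  counts <- colSums(M)
  truth <- structure(
    list(U = U, masks = masks, overlap = which(counts > 1),
         background = which(counts == 0), noise = noise,
         onsets = attr(U, "onsets"), spec = spec),
    class = "synthetic_truth")
  list(movie = movie, truth = truth)
}

#' Ground-truth label map of a synthetic movie
#'
#' Pixels in exactly one cluster get that cluster's id; overlap and
#' background pixels get 0. This is the map a perfect functional
#' segmentation (which discards mixed pixels) should recover.
#'
#' @param truth a `synthetic_truth`.
#' @return A [label_map].
#' @export
truth_label_map <- function(truth) {
  spec <- truth$spec
  lab <- integer(spec$height * spec$width)
  for (j in seq_along(truth$masks)) lab[truth$masks[[j]]] <- j
  lab[truth$overlap] <- 0L
  label_map(matrix(lab, spec$height, spec$width, byrow = TRUE))
}
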
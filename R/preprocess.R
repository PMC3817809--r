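#' Z-score normalise every pixel time series
#'
#' Each pixel column is centred by its mean and divided by its sample
#' (`n - 1` denominator) standard deviation, so transient glomerular
#' responses carry the same weight in every pixel regardless of resting
#' fluorescence. Zero-variance columns (dead camera pixels, masked regions)
#' become all-zero columns and are flagged rather than erroring; they can
#' then never win any later selection step.
#'
#' @param movie a [movie_matrix] with at least 2 frames.
#' @return list with elements `movie` (normalised [movie_matrix]) and
#'   `stats` (list `mu`, `sigma`, `zero_variance` logical vector).
#' @export
zscore <- function(movie) {
  A <- movie$data
  m <- nrow(A)
  if (m < 2L) stop("z-score needs at least 2 frames")
  mu <- colMeans(A)
  A <- sweep(A, 2L, mu, "-")
  sigma <- sqrt(colSums(A^2) / (m - 1))
  zero <- sigma <= 0
  sig <- ifelse(zero, 1, sigma)
  A <- sweep(A, 2L, sig, "/")
  if (any(zero)) A[, zero] <- 0
  out <- movie
  out$data <- A
  list(movie = out,
       stats = list(mu = mu, sigma = sigma, zero_variance = zero))
}

#' Stimulus window annotation
#'
#' Describes, for one concatenated recording segment, the baseline interval
#' preceding odour stimulation. Frames are 1-based and relative to the start
#' of the segment; the baseline is `[from, to]` inclusive and must end at or
#' before `onset`.
#'
#' @param segment 1-based segment index.
#' @param baseline length-2 integer vector `c(from, to)`, inclusive.
#' @param onset stimulus onset frame (segment-relative, 1-based).
#' @export
stimulus_window <- function(segment, baseline, onset) {
  baseline <- as.integer(baseline)
  if (length(baseline) != 2L || baseline[1L] > baseline[2L] || baseline[1L] < 1L)
    stop("baseline must be c(from, to) with 1 <= from <= to")
  if (onset < baseline[2L]) stop("stimulus onset precedes end of baseline")
  structure(list(segment = as.integer(segment), baseline = baseline,
                 onset = as.integer(onset)),
            class = "stimulus_window")
}

#' Baseline fold-change normalisation
#'
#' For every segment that has a stimulus window, subtracts each pixel's mean
#' over the pre-stimulus baseline interval from the whole segment; with
#' `divide = TRUE` the result is additionally divided by the baseline mean
#' (the Delta-F/F variant). Segments without a window pass through unchanged.
#'
#' @param movie a [movie_matrix].
#' @param windows list of [stimulus_window] objects.
#' @param divide divide by the baseline mean as well as subtracting it.
#' @return A [movie_matrix].
#' @export
fold_change <- function(movie, windows, divide = FALSE) {
  if (inherits(windows, "stimulus_window")) windows <- list(windows)
  A <- movie$data
  for (wnd in windows) {
    fr <- segment_frames(movie, wnd$segment)
    if (wnd$baseline[2L] > length(fr) || wnd$onset > length(fr))
      stop("stimulus window extends past segment ", wnd$segment,
           " (", length(fr), " frames)")
    base_rows <- fr[wnd$baseline[1L]:wnd$baseline[2L]]
    mu <- colMeans(A[base_rows, , drop = FALSE])
    A[fr, ] <- sweep(A[fr, , drop = FALSE], 2L, mu, "-")
    if (divide) {
      if (any(mu == 0)) {
        stop("zero baseline mean at pixel(s) ",
             paste(utils::head(which(mu == 0), 5L), collapse = ", "),
             "; cannot divide")
      }
      A[fr, ] <- sweep(A[fr, , drop = FALSE], 2L, mu, "/")
    }
  }
  out <- movie
  out$data <- A
  out
}

## 1-D truncated Gaussian kernel over an odd window; sums to 1
gauss_kernel_1d <- function(width) {
  sigma <- width / 4
  x <- seq.int(-(width %/% 2L), width %/% 2L)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

## dense 1-D convolution matrix with symmetric (reflect) padding
conv_matrix_1d <- function(size, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  C <- matrix(0, size, size)
  for (i in seq_len(size)) {
    for (j in seq_along(kernel)) {
      src <- i + j - half - 1L
      # symmetric reflection: ... 2 1 | 1 2 ... n | n n-1 ...
      if (src < 1L) src <- 1L - src
      if (src > size) src <- 2L * size + 1L - src
      C[i, src] <- C[i, src] + kernel[j]
    }
  }
  C
}

#' Spatial Gaussian smoothing of every frame
#'
#' Convolves each frame with a normalised 2-D Gaussian kernel truncated to a
#' `width x width` support (`sigma = width / 4`), with symmetric reflection
#' at the image borders. The kernel sums to 1, so flat regions and the
#' overall DC level are preserved. Used to trade spatial resolution for
#' noise suppression before decomposition at high noise levels.
#'
#' @param movie a [movie_matrix].
#' @param width odd kernel support in pixels (the field's usual choice is 7).
#' @return A [movie_matrix].
#' @export
spatial_gauss <- function(movie, width = 7L) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  if (width == 1L) return(movie)
  k <- gauss_kernel_1d(width)
  Cv <- conv_matrix_1d(movie$height, k)   # image rows
  Ch <- conv_matrix_1d(movie$width, k)    # image cols
  # row-major pixel order: frame vector = vec(t(img)); convolution acts as
  # (Cv kron Ch) on that vector; applied as two sparse passes
  Kh <- Matrix::kronecker(Matrix::Diagonal(movie$height), Matrix::Matrix(Ch))
  Kv <- Matrix::kronecker(Matrix::Matrix(Cv), Matrix::Diagonal(movie$width))
  out <- movie
  out$data <- as.matrix(movie$data %*% Matrix::t(Kh) %*% Matrix::t(Kv))
  out
}

#' Temporal moving-average filtering
#'
#' A centred moving average of odd width applied along time independently
#' within each recording segment, so no information bleeds across segment
#' boundaries. Frames near segment edges use symmetrically shrunken windows.
#'
#' @param movie a [movie_matrix].
#' @param width odd window length in frames, at most the shortest segment.
#' @return A [movie_matrix].
#' @export
temporal_filter <- function(movie, width) {
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  seg_len <- diff(movie$segment_bounds)
  if (width > min(seg_len))
    stop("width (", width, ") exceeds shortest segment (", min(seg_len), ")")
  if (width == 1L) return(movie)
  half <- width %/% 2L
  A <- movie$data
  out <- A
  for (s in seq_len(n_segments(movie))) {
    fr <- segment_frames(movie, s)
    seg <- A[fr, , drop = FALSE]
    cs <- rbind(0, apply(seg, 2L, cumsum))
    n <- nrow(seg)
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    out[fr, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1L)
  }
  res <- movie
  res$data <- out
  res
}

#' Elementwise arithmetic between two movies
#'
#' Adds, subtracts or takes the elementwise ratio of two movies of identical
#' shape. The ratio is how dual-excitation (e.g. 340/380 nm) recordings are
#' combined into a calcium-proportional signal.
#'
#' @param a,b [movie_matrix] objects of identical shape.
#' @param op `"add"`, `"subtract"` or `"ratio"`.
#' @return A [movie_matrix] with the geometry and segments of `a`.
#' @export
image_arithmetic <- function(a, b, op = c("add", "subtract", "ratio")) {
  op <- match.arg(op)
  if (!identical(dim(a$data), dim(b$data)) ||
      a$height != b$height || a$width != b$width)
    stop("shape mismatch between operands")
  out <- a
  out$data <- switch(op,
    add = a$data + b$data,
    subtract = a$data - b$data,
    ratio = {
      nz <- sum(b$data == 0)
      if (nz > 0L) stop("ratio: denominator is zero at ", nz, " entries")
      a$data / b$data
    })
  out
}

## integer-translate an h x w image by (dy, dx); vacated cells become NA
translate_image <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(NA_real_, h, w)
  src_r <- seq_len(h) - dy
  src_c <- seq_len(w) - dx
  ok_r <- src_r >= 1L & src_r <= h
  ok_c <- src_c >= 1L & src_c <= w
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}

#' Movement stabilisation across concatenated recordings
#'
#' Animal movement between recordings shows up as an integer translation of
#' each later segment relative to the first. For every segment after the
#' first, the translation `(dy, dx)` of the segment's mean frame relative to
#' the first segment's mean frame is estimated by exhaustive search over
#' `[-radius, radius]^2`, maximising the Pearson correlation on the
#' overlapping region; the segment is then shifted back by the inverse
#' translation. Vacated border pixels are filled with the segment's
#' per-pixel temporal mean at the same position. The reported shifts are the
#' estimated displacements (so a segment that drifted down 2 and left 1
#' reports `c(2, -1)`); the first segment always reports `c(0, 0)`.
#'
#' @param movie a [movie_matrix].
#' @param radius search radius in pixels; must be below `min(h, w) / 2`.
#' @return list with `movie` (aligned [movie_matrix]) and `shifts` (list of
#'   integer `c(dy, dx)` per segment).
#' @export
stabilise <- function(movie, radius = 10L) {
  radius <- as.integer(radius)
  ns <- n_segments(movie)
  shifts <- rep(list(c(0L, 0L)), ns)
  if (ns == 1L) return(list(movie = movie, shifts = shifts))
  if (radius >= min(movie$height, movie$width) / 2)
    stop("search radius must be below min(h, w) / 2")
  ref <- colMeans(movie$data[segment_frames(movie, 1L), , drop = FALSE])
  ref_img <- matrix(ref, movie$height, movie$width, byrow = TRUE)
  A <- movie$data
  for (s in 2L:ns) {
    fr <- segment_frames(movie, s)
    seg_mean <- matrix(colMeans(A[fr, , drop = FALSE]),
                       movie$height, movie$width, byrow = TRUE)
    best <- c(0L, 0L); best_cor <- -Inf
    for (dy in -radius:radius) {
      for (dx in -radius:radius) {
        # hypothesis: segment content = reference displaced by (dy, dx)
        shifted <- translate_image(ref_img, dy, dx)
        ok <- !is.na(shifted)
        cc <- suppressWarnings(stats::cor(shifted[ok], seg_mean[ok]))
        if (is.finite(cc) && cc > best_cor) {
          best_cor <- cc
          best <- c(dy, dx)
        }
      }
    }
    shifts[[s]] <- best
    if (any(best != 0L)) {
      fill <- colMeans(A[fr, , drop = FALSE])
      for (t in fr) {
        img <- matrix(A[t, ], movie$height, movie$width, byrow = TRUE)
        img <- translate_image(img, -best[1L], -best[2L])
        vac <- is.na(img)
        if (any(vac)) {
          fill_img <- matrix(fill, movie$height, movie$width, byrow = TRUE)
          img[vac] <- fill_img[vac]
        }
        A[t, ] <- flatten_frame(img)
      }
    }
  }
  out <- movie
  out$data <- A
  list(movie = out, shifts = shifts)
}
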
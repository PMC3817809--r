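#' Movie matrix container
#'
#' A calcium-imaging movie is represented as an `m x n` numeric matrix: one
#' row per frame, one column per pixel. Frames are flattened row-major, so
#' pixel `p` (1-based) sits at image row `(p - 1) %/% width + 1` and image
#' column `(p - 1) %% width + 1`. Every map and image produced by the package
#' uses this one convention.
#'
#' `segment_bounds` records concatenated recordings as 0-based frame offsets:
#' it starts at 0, ends at `m`, and is strictly increasing; segment `i` covers
#' frames `segment_bounds[i] + 1` to `segment_bounds[i + 1]` (1-based).
#'
#' @param data numeric matrix, frames by pixels; must be finite.
#' @param height,width image geometry in pixels; `height * width` must equal
#'   `ncol(data)`.
#' @param segment_bounds integer vector of segment offsets; default one
#'   segment spanning the whole movie.
#' @param frame_rate_hz optional positive frame rate.
#' @return An object of class `movie_matrix`.
#' @export
movie_matrix <- function(data, height, width, segment_bounds = NULL,
                         frame_rate_hz = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  m <- nrow(data)
  if (ncol(data) != height * width) {
    stop("ncol(data) [", ncol(data), "] != height * width [",
         height * width, "]")
  }
  if (any(!is.finite(data))) {
    bad <- which(!is.finite(data), arr.ind = TRUE)[1L, ]
    stop("movie contains non-finite values (first at frame ", bad[1L],
         ", pixel ", bad[2L], "); refusing to load")
  }
  if (is.null(segment_bounds)) segment_bounds <- c(0L, m)
  segment_bounds <- as.integer(segment_bounds)
  if (segment_bounds[1L] != 0L || segment_bounds[length(segment_bounds)] != m ||
      any(diff(segment_bounds) <= 0L)) {
    stop("segment_bounds must be strictly increasing, start at 0 and end at m")
  }
  if (!is.null(frame_rate_hz) && frame_rate_hz <= 0) {
    stop("frame_rate_hz must be positive")
  }
  structure(
    list(data = data, height = as.integer(height), width = as.integer(width),
         segment_bounds = segment_bounds, frame_rate_hz = frame_rate_hz),
    class = "movie_matrix"
  )
}

#' @export
print.movie_matrix <- function(x, ...) {
  cat("<movie_matrix> ", nrow(x$data), " frames x ", ncol(x$data),
      " pixels (", x$height, " x ", x$width, "), ",
      n_segments(x), " segment(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.movie_matrix <- function(x) dim(x$data)

#' Number of concatenated segments in a movie
#' @param movie a `movie_matrix`.
#' @export
n_segments <- function(movie) length(movie$segment_bounds) - 1L

#' Frame rows of a segment
#' @param movie a `movie_matrix`.
#' @param i segment index (1-based).
#' @return integer vector of 1-based frame indices.
#' @export
segment_frames <- function(movie, i) {
  b <- movie$segment_bounds
  if (i < 1L || i > length(b) - 1L) stop("segment index out of range")
  (b[i] + 1L):b[i + 1L]
}

#' Convert between pixel index and image coordinates
#'
#' Row-major flattening: `pixel_index(r, c, w) == (r - 1) * w + c`, 1-based.
#'
#' @param row,col 1-based image coordinates.
#' @param width image width.
#' @export
pixel_index <- function(row, col, width) (row - 1L) * width + col

#' @rdname pixel_index
#' @param p 1-based pixel index.
#' @return `pixel_coords` returns a two-column matrix of (row, col).
#' @export
pixel_coords <- function(p, width) {
  cbind(row = (p - 1L) %/% width + 1L, col = (p - 1L) %% width + 1L)
}

#' Extract one frame as an image matrix
#' @param movie a `movie_matrix`.
#' @param i frame index.
#' @return `height x width` matrix.
#' @export
get_frame <- function(movie, i) {
  matrix(movie$data[i, ], nrow = movie$height, ncol = movie$width,
         byrow = TRUE)
}

## flatten an h x w image matrix into a row-major pixel vector
flatten_frame <- function(img) as.vector(t(img))

#' Read an imaging movie
#'
#' Supported layouts: a multi-page grayscale TIFF stack (8/16-bit integer or
#' 32-bit float), or a delimited text matrix whose header line holds the image
#' height and width (`h,w`) followed by one comma-separated row of `h*w`
#' pixel values per frame.
#'
#' Integer TIFF pages are read as raw counts; float pages as stored. All
#' pages must share one resolution. Non-finite values are rejected.
#'
#' @param path file to read.
#' @param layout `"tiff_stack"` or `"delimited_matrix"`; default guesses from
#'   the file extension (`.tif`/`.tiff` vs anything else).
#' @return A [movie_matrix].
#' @export
read_movie <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (is.null(layout)) {
    layout <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
      "tiff_stack" else "delimited_matrix"
  }
  layout <- match.arg(layout, c("tiff_stack", "delimited_matrix"))
  if (layout == "tiff_stack") read_movie_tiff(path) else read_movie_csv(path)
}

read_movie_tiff <- function(path) {
  info <- tryCatch(tiff::readTIFF(path, all = TRUE, info = TRUE),
                   error = function(e) stop("unreadable TIFF '", path, "': ",
                                            conditionMessage(e)))
  if (!is.list(info)) info <- list(info)
  pages <- lapply(seq_along(info), function(i) {
    pg <- info[[i]]
    if (length(dim(pg)) == 3L) {
      if (dim(pg)[3L] == 1L) pg <- pg[, , 1L]
      else stop("page ", i, " of '", path, "' is not grayscale")
    }
    bits <- attr(pg, "bits.per.sample")
    if (!is.null(bits) && bits < 32L) {
      # integer samples: recover raw counts (readTIFF scales to [0,1])
      pg <- pg * (2^bits - 1)
      pg <- round(pg)
    }
    pg
  })
  dims <- vapply(pages, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    bad <- which(dims[1L, ] != dims[1L, 1L] | dims[2L, ] != dims[2L, 1L])[1L]
    stop("inconsistent page sizes in '", path, "': page ", bad, " is ",
         dims[1L, bad], "x", dims[2L, bad], ", page 1 is ",
         dims[1L, 1L], "x", dims[2L, 1L])
  }
  h <- dims[1L, 1L]; w <- dims[2L, 1L]
  data <- do.call(rbind, lapply(pages, flatten_frame))
  movie_matrix(data, height = h, width = w)
}

read_movie_csv <- function(path) {
  hdr <- scan(path, what = integer(), sep = ",", nlines = 1L, quiet = TRUE)
  if (length(hdr) != 2L || any(hdr < 1L)) {
    stop("line 1 of '", path, "' must hold two positive integers: height,width")
  }
  h <- hdr[1L]; w <- hdr[2L]
  data <- utils::read.table(path, sep = ",", skip = 1L, header = FALSE)
  data <- as.matrix(data)
  dimnames(data) <- NULL
  if (ncol(data) != h * w) {
    stop("'", path, "' rows have ", ncol(data),
         " values but header implies ", h * w)
  }
  movie_matrix(data, height = h, width = w)
}

#' Write an imaging movie
#'
#' `.csv` paths use the exact delimited layout of [read_movie] (header line
#' `h,w`, then one row per frame). `.tif`/`.tiff` paths write a 16-bit
#' multi-page TIFF after min-max scaling the whole movie to `[0, 1]`; this is
#' a lossy interchange/visualisation format — use CSV where exact values
#' matter.
#'
#' @param movie a [movie_matrix].
#' @param path destination; format chosen by extension.
#' @export
write_movie <- function(movie, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(movie$data)
    den <- if (rng[2L] > rng[1L]) rng[2L] - rng[1L] else 1
    pages <- lapply(seq_len(nrow(movie$data)), function(i) {
      (get_frame(movie, i) - rng[1L]) / den
    })
    ok <- tryCatch(tiff::writeTIFF(pages, path, bits.per.sample = 16L,
                                   compression = "none"),
                   error = function(e) stop("cannot write '", path, "': ",
                                            conditionMessage(e)))
    invisible(ok)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(movie$height, movie$width, sep = ","), con)
    utils::write.table(format(movie$data, digits = 17, trim = TRUE,
                              scientific = TRUE),
                       con, sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    invisible(TRUE)
  }
}

#' Concatenate movies recorded from the same animal
#'
#' Frames are stacked in order and each input's extent is recorded in
#' `segment_bounds`, so segment-aware steps (temporal filtering, baseline
#' windows, stabilisation) can respect recording boundaries.
#'
#' @param movies list of [movie_matrix] objects sharing one geometry.
#' @return A single [movie_matrix].
#' @export
concat_movies <- function(movies) {
  stopifnot(length(movies) >= 1L)
  h <- movies[[1L]]$height; w <- movies[[1L]]$width
  for (mv in movies) {
    if (mv$height != h || mv$width != w) {
      stop("geometry mismatch: expected ", h, "x", w, ", got ",
           mv$height, "x", mv$width)
    }
  }
  data <- do.call(rbind, lapply(movies, function(mv) mv$data))
  # interior bounds of each input are preserved as well
  bounds <- 0L
  for (mv in movies) {
    bounds <- c(bounds, bounds[length(bounds)] + mv$segment_bounds[-1L])
  }
  movie_matrix(data, height = h, width = w, segment_bounds = bounds,
               frame_rate_hz = movies[[1L]]$frame_rate_hz)
}

#' Write basis time series to CSV
#'
#' One column per signal, one row per frame, with a header row of signal ids.
#'
#' @param T numeric matrix, frames by signals (0 columns allowed).
#' @param path destination file.
#' @param ids optional character vector of column ids.
#' @export
write_timeseries <- function(T, path, ids = NULL) {
  T <- as.matrix(T)
  if (any(!is.finite(T))) stop("time series contain non-finite values")
  if (ncol(T) == 0L) {
    writeLines("", path)
    return(invisible(TRUE))
  }
  if (is.null(ids)) ids <- paste0("signal_", seq_len(ncol(T)))
  df <- as.data.frame(T)
  names(df) <- ids
  utils::write.csv(format(df, digits = 17, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
}

#' Read basis time series written by [write_timeseries]
#' @param path CSV file.
#' @return numeric matrix with signal ids as column names.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as.matrix(df)
}

#' Label maps
#'
#' A label map assigns each pixel of an `h x w` image to a cluster id in
#' `1..c`, with 0 meaning unassigned ("white" in a glomerular map). Stored as
#' an integer matrix with class `label_map`.
#'
#' @param labels integer `h x w` matrix, values in `0..c`.
#' @export
label_map <- function(labels) {
  labels <- as.matrix(labels)
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  if (any(labels < 0L)) stop("label values must be >= 0")
  structure(labels, class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat("<label_map> ", nrow(x), " x ", ncol(x), ", ",
      length(setdiff(unique(as.vector(x)), 0L)), " clusters, ",
      sum(x == 0L), " unassigned pixel(s)\n", sep = "")
  invisible(x)
}

#' Write / read a label map
#'
#' `.tif`/`.tiff` paths store labels as a 16-bit integer TIFF (exact for up
#' to 65535 clusters); other paths store a plain CSV of integers, one image
#' row per line. Both round-trip exactly.
#'
#' @param map a [label_map].
#' @param path destination; format chosen by extension.
#' @export
write_label_map <- function(map, path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (max(map) > 65535L) stop("more than 65535 labels; use CSV")
    img <- unclass(map) / 65535
    tiff::writeTIFF(img, path, bits.per.sample = 16L, compression = "none")
  } else {
    utils::write.table(unclass(map), path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(TRUE)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    img <- tiff::readTIFF(path, as.is = TRUE)
    label_map(img)
  } else {
    label_map(as.matrix(utils::read.table(path, sep = ",", header = FALSE)))
  }
}
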
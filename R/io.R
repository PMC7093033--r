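#' Movie container
#'
#' A fluorescence movie as a frame-by-pixel matrix plus its pixel geometry.
#' Frames are vectorized row-major: pixel (row i, column j) maps to column
#' `(i - 1) * width + j`.
#'
#' @param frames `R x d_y` numeric matrix.
#' @param height,width Pixel grid with `height * width = d_y`.
#' @param frame_rate Frames per second (optional; `delta = 1 / frame_rate`).
#' @param meta Free-form provenance list.
#' @return An object of class `movie_container`.
#' @export
movie_container <- function(frames, height, width, frame_rate = NULL,
                            meta = list()) {
  assert_matrix(frames, ncol = height * width, name = "frames")
  if (any(!is.finite(frames))) stop("movie frames must be finite")
  structure(list(frames = frames, height = as.integer(height),
                 width = as.integer(width), frame_rate = frame_rate,
                 meta = meta),
            class = "movie_container")
}

#' @export
print.movie_container <- function(x, ...) {
  cat(sprintf("<movie_container> %d frames of %d x %d px%s\n",
              nrow(x$frames), x$height, x$width,
              if (!is.null(x$frame_rate)) sprintf(" at %g Hz", x$frame_rate)
              else ""))
  invisible(x)
}

#' Read a movie from a multi-page TIFF
#'
#' Grayscale multi-page TIFFs only. Integer samples (e.g. uint16) are
#' converted to numeric without rescaling; float32 TIFFs are read natively.
#' Movies written by [write_movie()] carry a JSON sidecar with the affine
#' offset/scale used for storage (and the frame rate), which is applied on
#' reading.
#'
#' @param path TIFF file path.
#' @param frame_rate Frames per second (overridden by a sidecar value).
#' @return A [movie_container()].
#' @export
read_movie <- function(path, frame_rate = NULL) {
  has_sidecar <- file.exists(paste0(path, ".json"))
  pages <- if (has_sidecar) {
    # our own files: samples are the affine-normalized values in [0, 1]
    tiff::readTIFF(path, all = TRUE)
  } else {
    # foreign files: raw integer samples unscaled, floats natively
    tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
             error = function(e) tiff::readTIFF(path, all = TRUE))
  }
  if (length(pages) == 0) stop("empty TIFF")
  d <- dim(pages[[1]])
  if (length(d) != 2)
    stop("multichannel (RGB) TIFF input is not supported; supply grayscale")
  frames <- t(vapply(pages, function(p) as.numeric(t(p)),
                     numeric(prod(d))))
  meta <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    frames <- frames * sc$scale + sc$offset
    frame_rate <- sc$frame_rate %||% frame_rate
    meta <- c(meta, list(sidecar = sc))
  }
  movie_container(frames, d[1], d[2], frame_rate, meta)
}

#' Write a movie to a multi-page TIFF
#'
#' Stores frames as 32-bit samples after an affine map into the unit interval and
#' records the inverse map (offset, scale) with the frame geometry in a JSON
#' sidecar `<path>.json`, so that [read_movie()] restores the original
#' values (to within one part in 2^32 of the value range). Writing is atomic
#' (temporary file then rename).
#'
#' @param movie A [movie_container()] or a plain `R x d_y` matrix (then
#'   `height`/`width` are required).
#' @param path Output TIFF path.
#' @param height,width Pixel grid when `movie` is a plain matrix.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, height = NULL, width = NULL) {
  if (!inherits(movie, "movie_container")) {
    if (is.null(height) || is.null(width))
      stop("'height' and 'width' are required for a plain matrix")
    movie <- movie_container(movie, height, width)
  }
  lo <- min(movie$frames)
  hi <- max(movie$frames)
  scale <- max(hi - lo, 1e-300)
  scaled <- (movie$frames - lo) / scale
  pages <- lapply(seq_len(nrow(scaled)), function(r)
    matrix(scaled[r, ], movie$height, movie$width, byrow = TRUE))
  tmp <- paste0(path, ".tmp")
  tiff::writeTIFF(pages, tmp, bits.per.sample = 32L)
  file.rename(tmp, path)
  sidecar <- list(offset = lo, scale = scale, height = movie$height,
                  width = movie$width, frame_rate = movie$frame_rate)
  tmp2 <- paste0(path, ".json.tmp")
  jsonlite::write_json(sidecar, tmp2, auto_unbox = TRUE, digits = NA,
                       null = "null")
  file.rename(tmp2, paste0(path, ".json"))
  invisible(path)
}

#' Read a stimulus series from CSV
#'
#' Expects a header `frame,x` (or `frame,x1,...` for multivariate stimuli)
#' with consecutive frames starting at 1. The sampling interval comes from
#' `delta` or `frame_rate`.
#'
#' @param path CSV path.
#' @param delta Sampling interval in seconds.
#' @param frame_rate Alternative to `delta` (`delta = 1 / frame_rate`).
#' @param circular Wrap values into `(-pi, pi]` (von Mises stimuli)?
#' @param n_frames If given, validate the frame count against the movie.
#' @return A [stimulus_series()].
#' @export
read_stimulus_csv <- function(path, delta = NULL, frame_rate = NULL,
                              circular = FALSE, n_frames = NULL) {
  if (is.null(delta)) {
    if (is.null(frame_rate)) stop("supply 'delta' or 'frame_rate'")
    delta <- 1 / frame_rate
  }
  df <- utils::read.csv(path)
  if (!"frame" %in% names(df)) stop("stimulus CSV must have a 'frame' column")
  xcols <- setdiff(names(df), "frame")
  if (length(xcols) == 0) stop("stimulus CSV has no stimulus columns")
  if (anyNA(df)) stop("stimulus CSV contains missing values")
  if (any(df$frame != seq_len(nrow(df))))
    stop("'frame' must be consecutive integers starting at 1")
  if (!is.null(n_frames) && nrow(df) != n_frames)
    stop(sprintf("stimulus has %d frames but the movie has %d",
                 nrow(df), n_frames))
  vals <- if (length(xcols) == 1) df[[xcols]] else as.matrix(df[xcols])
  stimulus_series(vals, delta, circular = circular)
}

#' Write a stimulus series to CSV
#'
#' @param stim A [stimulus_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stimulus_csv <- function(stim, path) {
  stopifnot(inherits(stim, "stimulus_series"))
  df <- if (stim$d_x == 1) {
    data.frame(frame = seq_len(stim$R), x = stim$values)
  } else {
    out <- data.frame(frame = seq_len(stim$R))
    for (j in seq_len(stim$d_x)) out[[paste0("x", j)]] <- stim$values[, j]
    out
  }
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Tile a movie into spatial patches
#'
#' Splits the field of view into independent patches (default overlap 0,
#' i.e. a partition) for piecewise fitting of large movies. Placement
#' records map per-patch pixels, footprints and ROIs back to global
#' coordinates; stitching of per-patch results is concatenation with
#' coordinate offsets (no cross-patch component merging).
#'
#' @param movie A [movie_container()].
#' @param patch_height,patch_width Patch size in pixels (tail patches may be
#'   smaller).
#' @param overlap Overlap between neighbouring patches in pixels
#'   (default 0).
#' @return List of `list(movie = movie_container, placement = list(row0,
#'   col0, rows, cols))`, one per patch, in row-major patch order.
#' @export
patch_movie <- function(movie, patch_height, patch_width, overlap = 0) {
  stopifnot(inherits(movie, "movie_container"))
  if (patch_height > movie$height || patch_width > movie$width)
    stop("patch size exceeds the frame size")
  if (overlap < 0) stop("'overlap' must be non-negative")
  starts <- function(total, size, ov) {
    if (size >= total) return(1L)
    s <- seq(1L, total - size + 1L, by = max(size - ov, 1L))
    if (s[length(s)] + size - 1L < total) s <- c(s, total - size + 1L)
    unique(s)
  }
  r0 <- starts(movie$height, patch_height, overlap)
  c0 <- starts(movie$width, patch_width, overlap)
  out <- list()
  for (i in r0) for (j in c0) {
    rows <- i:min(i + patch_height - 1L, movie$height)
    cols <- j:min(j + patch_width - 1L, movie$width)
    cols_idx <- as.integer(outer(cols, (rows - 1L) * movie$width, "+"))
    sub <- movie$frames[, cols_idx, drop = FALSE]
    out[[length(out) + 1]] <- list(
      movie = movie_container(sub, length(rows), length(cols),
                              movie$frame_rate,
                              c(movie$meta, list(patch_origin = c(i, j)))),
      placement = list(row0 = i, col0 = j, rows = rows, cols = cols))
  }
  out
}

#' Map a per-patch footprint back to the global pixel grid
#'
#' @param values Per-patch pixel vector (row-major within the patch).
#' @param placement A placement record from [patch_movie()].
#' @param height,width Global frame size.
#' @return Global pixel vector (row-major), zero outside the patch.
#' @export
place_patch <- function(values, placement, height, width) {
  out <- numeric(height * width)
  idx <- as.integer(outer(placement$cols, (placement$rows - 1L) * width, "+"))
  out[idx] <- values
  out
}

#' Save / load fitted results
#'
#' Results (posterior, deconvolution, ground truth) are R lists; they are
#' stored as RDS with an atomic write, plus a small JSON summary next to the
#' file (`<path>.json`: class, dimensions, active components, ELBO trace).
#'
#' @param object Object to save.
#' @param path Output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_result <- function(object, path) {
  tmp <- paste0(path, ".tmp")
  saveRDS(object, tmp)
  file.rename(tmp, path)
  summ <- list(class = class(object)[1])
  if (inherits(object, "mpp_posterior"))
    summ <- c(summ, list(R = object$R, d_kappa = object$d_kappa,
                         K = object$K, active = which(object$active),
                         elbo_trace = object$elbo_trace))
  if (inherits(object, "mpp_deconvolution"))
    summ <- c(summ, list(components = object$component_ids,
                         n_spikes = sum(lengths(object$spikes))))
  tmp2 <- paste0(path, ".json.tmp")
  jsonlite::write_json(summ, tmp2, auto_unbox = TRUE, digits = NA)
  file.rename(tmp2, paste0(path, ".json"))
  invisible(path)
}
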
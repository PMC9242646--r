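#' Movie stack container
#'
#' Time-ordered 2-D intensity frames with physical calibration.
#'
#' @param frames Numeric array `height x width x T`, nonnegative intensities.
#' @param pixel_size um/pixel (> 0).
#' @param frame_interval s/frame (> 0).
#' @param label Free-text label.
#' @return Object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size, frame_interval, label = "") {
  if (length(dim(frames)) != 3L || dim(frames)[3] < 2L)
    stop("frames must be a H x W x T array with T >= 2")
  if (pixel_size <= 0 || frame_interval <= 0)
    stop("calibration values must be strictly positive")
  m <- list(frames = frames, pixel_size = pixel_size,
            frame_interval = frame_interval, label = label)
  class(m) <- "movie_stack"
  m
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack '%s': %d frames of %dx%d px, %.3g um/px, %.3g s/frame\n",
              x$label, d[3], d[1], d[2], x$pixel_size, x$frame_interval))
  invisible(x)
}

#' Number of frames in a movie
#' @param movie A `movie_stack`.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Movie duration in minutes
#' @param movie A `movie_stack`.
#' @export
movie_duration_min <- function(movie) n_frames(movie) * movie$frame_interval / 60

#' Write a movie as a multi-page TIFF
#'
#' Intensities are stored as 16-bit; the calibration is embedded as a JSON
#' string in the TIFF description tag together with the intensity scale.
#'
#' @param movie A `movie_stack`.
#' @param file Output path.
#' @param max_intensity Intensity mapped to the 16-bit ceiling; defaults to
#'   the movie maximum.
#' @export
write_movie_tiff <- function(movie, file, max_intensity = NULL) {
  if (is.null(max_intensity)) max_intensity <- max(movie$frames)
  if (max_intensity <= 0) max_intensity <- 1
  desc <- jsonlite::toJSON(list(pixel_size_um = movie$pixel_size,
                                frame_interval_s = movie$frame_interval,
                                intensity_scale = max_intensity,
                                label = movie$label), auto_unbox = TRUE)
  pages <- lapply(seq_len(n_frames(movie)), function(t)
    pmin(pmax(movie$frames[, , t] / max_intensity, 0), 1))
  tiff::writeTIFF(pages, file, bits.per.sample = 16L,
                  description = as.character(desc))
  invisible(file)
}

#' Read a movie written by [write_movie_tiff()]
#' @param file TIFF path.
#' @return A `movie_stack` with intensities restored to their original scale.
#' @export
read_movie_tiff <- function(file) {
  pages <- tiff::readTIFF(file, all = TRUE, info = TRUE)
  info <- attr(pages[[1]], "description")
  meta <- list(pixel_size_um = 1, frame_interval_s = 1, intensity_scale = 1, label = "")
  if (!is.null(info) && nzchar(info))
    meta <- utils::modifyList(meta, jsonlite::fromJSON(info))
  frames <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * meta$intensity_scale
  movie_stack(frames, meta$pixel_size_um, meta$frame_interval_s, meta$label)
}

# Add a 2-D Gaussian spot in place (used by the generators). Returns frame.
add_gaussian_spot <- function(frame, x, y, amplitude, sigma_px) {
  h <- nrow(frame); w <- ncol(frame)
  r <- ceiling(3 * sigma_px)
  # pixel centers at integer coordinates, 0-based (x = column, y = row)
  cx <- round(x); cy <- round(y)
  xs <- max(0, cx - r):min(w - 1, cx + r)
  ys <- max(0, cy - r):min(h - 1, cy + r)
  if (!length(xs) || !length(ys)) return(frame)
  gx <- exp(-((xs - x)^2) / (2 * sigma_px^2))
  gy <- exp(-((ys - y)^2) / (2 * sigma_px^2))
  frame[ys + 1L, xs + 1L] <- frame[ys + 1L, xs + 1L] + amplitude * outer(gy, gx)
  frame
}
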
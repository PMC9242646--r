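#' Build a kymograph along a microtubule path
#'
#' Each cell (frame, arclength bin) is the maximum intensity over a
#' `width`-pixel transect perpendicular to the path at that arclength,
#' evaluated with bilinear sub-pixel interpolation. The maximum (rather than
#' the mean) over the transect preserves dim moving spots. Bin size equals
#' the pixel size.
#'
#' @param movie A `movie_stack`.
#' @param path An `mt_path` inside the frame bounds.
#' @param width Odd transect width in pixels (default 5).
#' @return Object of class `kymograph`: `matrix` (rows = frames, cols =
#'   arclength bins), `bin_size` (um), `path_id`, `width`.
#' @export
build_kymograph <- function(movie, path, width = 5L) {
  stopifnot(inherits(movie, "movie_stack"), inherits(path, "mt_path"))
  width <- as.integer(width)
  if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
  bin_size <- movie$pixel_size
  L_um <- path_length_um(path, movie$pixel_size)
  n_bins <- ceiling(L_um / bin_size)
  h <- dim(movie$frames)[1]; w <- dim(movie$frames)[2]; T <- n_frames(movie)

  # sample coordinates: for each bin, `width` points along the unit normal.
  # Bin j (0-based) is sampled at arclength j px, so an emitter at arclength
  # s falls in bin floor(s / bin_size).
  s_px <- seq_len(n_bins) - 1
  pt <- path_point_at(path, s_px, tangent = TRUE)
  nx <- -pt$tangent[, 2]; ny <- pt$tangent[, 1] # unit normal
  off <- seq(-(width - 1L) / 2, (width - 1L) / 2)
  X <- outer(pt$position[, "x"], rep(1, width)) + outer(nx, off)
  Y <- outer(pt$position[, "y"], rep(1, width)) + outer(ny, off)
  if (any(X < 0 | X > w - 1 | Y < 0 | Y > h - 1))
    stop("path (with transect width ", width, ") exits the image")

  x0 <- floor(X); y0 <- floor(Y)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- X - x0; fy <- Y - y0
  # linear indices into a HxW matrix (column-major, 0-based coords)
  i00 <- y0 + 1L + x0 * h; i10 <- y1 + 1L + x0 * h
  i01 <- y0 + 1L + x1 * h; i11 <- y1 + 1L + x1 * h
  w00 <- (1 - fy) * (1 - fx); w10 <- fy * (1 - fx)
  w01 <- (1 - fy) * fx;       w11 <- fy * fx

  kymo <- matrix(0, nrow = T, ncol = n_bins)
  for (t in seq_len(T)) {
    f <- movie$frames[, , t]
    vals <- f[i00] * w00 + f[i10] * w10 + f[i01] * w01 + f[i11] * w11
    dim(vals) <- dim(X)
    kymo[t, ] <- apply(vals, 1L, max)
  }
  k <- list(matrix = kymo, bin_size = bin_size, path_id = path$id, width = width)
  class(k) <- "kymograph"
  k
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("kymograph of path '%s': %d frames x %d bins (%.3g um/bin, width %d px)\n",
              x$path_id, nrow(x$matrix), ncol(x$matrix), x$bin_size, x$width))
  invisible(x)
}

#' Detection parameters for kymograph event tracing
#'
#' @param threshold Absolute intensity threshold for peak detection; `NULL`
#'   derives `median + k_mad * mad` from the kymograph itself.
#' @param k_mad Robust threshold multiplier used when `threshold` is `NULL`.
#' @param min_separation Minimum distance (bins) between peaks in one frame.
#' @param max_jump Maximum linking distance in bins per frame.
#' @param max_gap Frames a track may go undetected before it is closed.
#' @param centroid_halfwidth Half-width (bins) of the window used for the
#'   intensity-weighted centroid refinement.
#' @export
detection_params <- function(threshold = NULL, k_mad = 6, min_separation = 3L,
                             max_jump = 5, max_gap = 2L, centroid_halfwidth = 3L) {
  list(threshold = threshold, k_mad = k_mad,
       min_separation = as.integer(min_separation), max_jump = max_jump,
       max_gap = as.integer(max_gap),
       centroid_halfwidth = as.integer(centroid_halfwidth))
}

#' Trace motility events on a kymograph
#'
#' Detects intensity peaks per frame, links them across frames by nearest
#' neighbour within `max_jump` bins (tolerating up to `max_gap` missed
#' frames, interpolated linearly), and refines positions to sub-bin accuracy
#' with background-subtracted intensity-weighted centroids. Events touching
#' the first or last frame are flagged censored.
#'
#' @param kymo A `kymograph`.
#' @param detection A [detection_params()] list.
#' @return List of `motility_event` objects; empty list for featureless
#'   input. Each event carries `path_id`, `start_frame`, `end_frame`
#'   (0-based, inclusive), `positions` (arclength um per frame),
#'   `mean_spot_intensity`, and `censored`.
#' @export
trace_events <- function(kymo, detection = detection_params()) {
  stopifnot(inherits(kymo, "kymograph"))
  m <- kymo$matrix
  if (!length(m)) stop("empty kymograph")
  T <- nrow(m); nb <- ncol(m)
  bg <- stats::median(m)
  thr <- detection$threshold
  if (is.null(thr)) thr <- bg + detection$k_mad * stats::mad(m)

  peaks_by_frame <- lapply(seq_len(T), function(t)
    find_row_peaks(m[t, ], thr, detection$min_separation))

  hw <- detection$centroid_halfwidth
  tracks <- list()   # each: list(frames, bins, peak_vals, last_frame)
  open_idx <- integer(0)
  for (t in seq_len(T)) {
    pk <- peaks_by_frame[[t]]
    used <- rep(FALSE, length(pk))
    if (length(open_idx)) {
      # greedy nearest-neighbour matching, best matches first
      cand <- expand.grid(tr = seq_along(open_idx), pk = seq_along(pk))
      if (nrow(cand)) {
        lastb <- vapply(open_idx, function(i) tracks[[i]]$bins[length(tracks[[i]]$bins)], numeric(1))
        lastf <- vapply(open_idx, function(i) tracks[[i]]$frames[length(tracks[[i]]$frames)], numeric(1))
        cand$d <- abs(lastb[cand$tr] - pk[cand$pk])
        cand$allow <- detection$max_jump * (t - lastf[cand$tr])
        cand <- cand[cand$d <= cand$allow, , drop = FALSE]
        cand <- cand[order(cand$d), , drop = FALSE]
        taken_tr <- rep(FALSE, length(open_idx))
        for (r in seq_len(nrow(cand))) {
          i <- cand$tr[r]; j <- cand$pk[r]
          if (taken_tr[i] || used[j]) next
          taken_tr[i] <- TRUE; used[j] <- TRUE
          ti <- open_idx[i]
          tracks[[ti]]$frames <- c(tracks[[ti]]$frames, t)
          tracks[[ti]]$bins <- c(tracks[[ti]]$bins, pk[j])
          tracks[[ti]]$peak_vals <- c(tracks[[ti]]$peak_vals, m[t, pk[j]])
        }
      }
    }
    for (j in seq_along(pk)) if (!used[j]) {
      tracks[[length(tracks) + 1L]] <- list(frames = t, bins = pk[j],
                                            peak_vals = m[t, pk[j]])
    }
    # close stale tracks
    open_idx <- which(vapply(tracks, function(tr)
      t - tr$frames[length(tr$frames)] <= detection$max_gap, logical(1)))
  }

  events <- list()
  for (tr in tracks) {
    if (length(tr$frames) < 2L) next
    f0 <- tr$frames[1]; f1 <- tr$frames[length(tr$frames)]
    all_f <- f0:f1
    bins <- stats::approx(tr$frames, tr$bins, xout = all_f)$y
    # centroid refinement per frame
    pos_bin <- vapply(seq_along(all_f), function(k) {
      t <- all_f[k]; b <- round(bins[k])
      jj <- max(1L, b - hw):min(nb, b + hw)
      wgt <- pmax(m[t, jj] - bg, 0)
      if (sum(wgt) == 0) return(bins[k])
      sum(jj * wgt) / sum(wgt)
    }, numeric(1))
    ev <- list(path_id = kymo$path_id, start_frame = f0 - 1L, end_frame = f1 - 1L,
               positions = (pos_bin - 1) * kymo$bin_size,
               mean_spot_intensity = mean(tr$peak_vals) - bg,
               censored = (f0 == 1L) || (f1 == T),
               class = NA_character_)
    class(ev) <- "motility_event"
    events[[length(events) + 1L]] <- ev
  }
  events
}

# Local maxima of a row above thr, with a minimum mutual separation;
# brighter peaks win ties.
find_row_peaks <- function(row, thr, min_sep) {
  n <- length(row)
  if (n < 3L) return(integer(0))
  is_pk <- row > thr &
    row >= c(-Inf, row[-n]) &
    row > c(row[-1], -Inf)
  idx <- which(is_pk)
  if (length(idx) <= 1L) return(idx)
  idx <- idx[order(row[idx], decreasing = TRUE)]
  keep <- logical(0); kept <- integer(0)
  for (i in idx) {
    if (!length(kept) || all(abs(kept - i) >= min_sep)) kept <- c(kept, i)
  }
  sort(kept)
}

#' @export
print.motility_event <- function(x, ...) {
  cat(sprintf("motility_event on '%s': frames %d-%d, class %s%s\n",
              x$path_id, x$start_frame, x$end_frame,
              ifelse(is.na(x$class), "<unclassified>", x$class),
              if (isTRUE(x$censored)) " (censored)" else ""))
  invisible(x)
}
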
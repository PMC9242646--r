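#' Synaptonemal-complex axis trace
#'
#' @param id Character identifier.
#' @param vertices Polyline vertices (n x 2 matrix, pixel coordinates).
#' @return Object of class `axis_trace` with `endpoints` = first and last
#'   vertices.
#' @export
axis_trace <- function(id, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    stop("an axis trace needs >= 2 vertices")
  colnames(vertices) <- c("x", "y")
  tr <- list(id = as.character(id), vertices = vertices,
             endpoints = vertices[c(1L, nrow(vertices)), , drop = FALSE])
  class(tr) <- "axis_trace"
  tr
}

#' Detect telomeric points as axis endpoints
#'
#' Telomeric regions are defined as the ends of the SYCP3 axis signals.
#' With trace input, returns both endpoints of every trace. With an image,
#' the above-threshold axes are skeletonized (Zhang-Suen thinning) and
#' skeleton endpoints (pixels with exactly one 8-connected neighbour) are
#' returned; closed-loop skeletons yield no endpoints and are flagged in
#' the `flagged_loops` attribute rather than silently dropped.
#'
#' @param x List of `axis_trace`, or a numeric matrix (SYCP3 plane).
#' @param threshold Image input only: absolute threshold (`NULL` = Otsu).
#' @param min_size Image input only: minimum axis component area (px).
#' @return data.frame with columns `axis_id`, `x_px`, `y_px` (one row per
#'   endpoint); attribute `flagged_loops` holds ids of closed-loop
#'   components.
#' @export
detect_axis_endpoints <- function(x, threshold = NULL, min_size = 30L) {
  if (is.list(x) && all(vapply(x, inherits, logical(1), "axis_trace"))) {
    out <- do.call(rbind, lapply(x, function(tr)
      data.frame(axis_id = tr$id, x_px = tr$endpoints[, "x"],
                 y_px = tr$endpoints[, "y"])))
    rownames(out) <- NULL
    attr(out, "flagged_loops") <- character(0)
    return(out)
  }
  if (!is.matrix(x)) stop("x must be a list of axis_trace or an image matrix")
  lab <- segment_nucleus(x, threshold = threshold, min_size = min_size)
  pts <- list(); loops <- character(0)
  for (i in seq_len(max(lab))) {
    comp <- lab == i
    skel <- zhang_suen_thin(comp)
    ends <- skeleton_endpoints(skel)
    id <- sprintf("axis%02d", i)
    if (!nrow(ends)) { loops <- c(loops, id); next }
    ref <- t(apply(ends, 1L, refine_axis_tip, skel = skel, plane = x))
    pts[[length(pts) + 1L]] <- data.frame(axis_id = id,
                                          x_px = ref[, 1], y_px = ref[, 2])
  }
  out <- if (length(pts)) do.call(rbind, pts) else
    data.frame(axis_id = character(0), x_px = numeric(0), y_px = numeric(0))
  rownames(out) <- NULL
  attr(out, "flagged_loops") <- loops
  out
}

# Zhang-Suen binary thinning; mask is a logical matrix.
zhang_suen_thin <- function(mask) {
  img <- mask > 0
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- img
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    rs <- (1 + max(0, dr)):(nrow(m) + min(0, dr))
    cs <- (1 + max(0, dc)):(ncol(m) + min(0, dc))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1);  p6 <- shift(pad, 1, 0);  p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      A <- matrix(0L, nrow(pad), ncol(pad))
      for (k in 1:8) A <- A + (!seqs[[k]] & seqs[[k + 1]])
      if (step == 1) {
        cond <- pad & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- pad & B >= 2 & B <= 6 & A == 1 & !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { pad[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)]
}

# Refine a skeleton endpoint to the sub-pixel axis terminus: walk outward
# along the local skeleton direction and place the tip at the half-maximum
# intensity crossing (the edge response of a PSF-convolved line end).
# `end_rc` is (row, col) 1-based; returns (x, y) 0-based pixel coordinates.
refine_axis_tip <- function(end_rc, skel, plane) {
  e <- c(end_rc[2] - 1, end_rc[1] - 1)          # (x, y), 0-based
  # farthest skeleton pixel within 5 steps of the endpoint gives direction
  h <- nrow(skel); w <- ncol(skel)
  visited <- matrix(FALSE, h, w)
  frontier <- matrix(end_rc, ncol = 2)
  visited[end_rc[1], end_rc[2]] <- TRUE
  inner <- end_rc
  for (step in 1:5) {
    nxt <- NULL
    for (k in seq_len(nrow(frontier))) {
      r <- frontier[k, 1]; c <- frontier[k, 2]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (skel[rr, cc] && !visited[rr, cc]) {
          visited[rr, cc] <- TRUE
          nxt <- rbind(nxt, c(rr, cc))
        }
      }
    }
    if (is.null(nxt)) break
    inner <- nxt[1, ]
    frontier <- nxt
  }
  d <- e - c(inner[2] - 1, inner[1] - 1)
  nd <- sqrt(sum(d^2))
  if (nd == 0) return(e)
  d <- d / nd
  ts <- seq(-2, 8, by = 0.25)
  xs <- e[1] + ts * d[1]; ys <- e[2] + ts * d[2]
  ok <- xs >= 0 & xs <= ncol(plane) - 1 & ys >= 0 & ys <= nrow(plane) - 1
  ts <- ts[ok]; xs <- xs[ok]; ys <- ys[ok]
  vals <- bilinear_at(plane, xs, ys)
  plateau <- max(vals[ts <= 0])
  bgv <- min(vals)
  half <- (plateau + bgv) / 2
  below <- which(ts > -1 & vals < half)
  if (!length(below)) return(e)
  j <- below[1]
  if (j == 1) return(e)
  f <- (vals[j - 1] - half) / (vals[j - 1] - vals[j])
  t_star <- ts[j - 1] + f * (ts[j] - ts[j - 1])
  e + t_star * d
}

# Bilinear interpolation of matrix values at 0-based (x, y).
bilinear_at <- function(plane, x, y) {
  h <- nrow(plane); w <- ncol(plane)
  x0 <- pmin(pmax(floor(x), 0), w - 1); y0 <- pmin(pmax(floor(y), 0), h - 1)
  x1 <- pmin(x0 + 1, w - 1); y1 <- pmin(y0 + 1, h - 1)
  fx <- x - x0; fy <- y - y0
  plane[cbind(y0 + 1, x0 + 1)] * (1 - fy) * (1 - fx) +
    plane[cbind(y1 + 1, x0 + 1)] * fy * (1 - fx) +
    plane[cbind(y0 + 1, x1 + 1)] * (1 - fy) * fx +
    plane[cbind(y1 + 1, x1 + 1)] * fy * fx
}

# Skeleton pixels with exactly one 8-connected neighbour; returns (row, col).
skeleton_endpoints <- function(skel) {
  h <- nrow(skel); w <- ncol(skel)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- skel
  nb <- matrix(0L, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- nb + pad[(2:(h + 1)) + dr, (2:(w + 1)) + dc]
  }
  which(skel & nb == 1L, arr.ind = TRUE)
}

#' Measure one focus with local background subtraction
#'
#' Raw intensity is the mean inside a disk aperture at the point; the local
#' background is the mean in a surrounding annulus, excluding any pixel that
#' falls inside another focus's aperture; corrected = raw - background.
#'
#' @param plane Intensity matrix.
#' @param point Numeric `c(x, y)` in pixel coordinates (0-based).
#' @param pixel_size um/pixel.
#' @param aperture_radius Aperture radius, um.
#' @param bg_inner,bg_outer Background annulus radii, um
#'   (`bg_outer > bg_inner >= aperture_radius`).
#' @param other_points Optional matrix/data.frame of other focus centers
#'   (columns x, y) whose apertures are excluded from the background.
#' @return List of class `focus_measurement`: `x_px`, `y_px`, `raw`,
#'   `background`, `corrected`.
#' @export
measure_focus <- function(plane, point, pixel_size, aperture_radius = 0.4,
                          bg_inner = 0.5, bg_outer = 0.8, other_points = NULL) {
  if (!(bg_outer > bg_inner && bg_inner >= aperture_radius))
    stop("annulus radii must satisfy outer > inner >= aperture_radius")
  h <- nrow(plane); w <- ncol(plane)
  x <- point[1]; y <- point[2]
  r_ap <- aperture_radius / pixel_size
  r_in <- bg_inner / pixel_size
  r_out <- bg_outer / pixel_size
  if (x - r_ap < 0 || x + r_ap > w - 1 || y - r_ap < 0 || y + r_ap > h - 1)
    stop("aperture out of bounds")
  xr <- max(0, floor(x - r_out)):min(w - 1, ceiling(x + r_out))
  yr <- max(0, floor(y - r_out)):min(h - 1, ceiling(y + r_out))
  d <- sqrt(outer((yr - y)^2, (xr - x)^2, "+"))
  sub <- plane[yr + 1L, xr + 1L, drop = FALSE]
  ap <- d <= r_ap
  ann <- d > r_in & d <= r_out
  if (!is.null(other_points) && nrow(other_points) > 0) {
    for (k in seq_len(nrow(other_points))) {
      dx <- outer((yr - other_points[k, 2])^2, (xr - other_points[k, 1])^2, "+")
      ann <- ann & sqrt(dx) > r_ap
    }
  }
  if (!any(ann)) stop("background annulus fully occluded by other foci")
  out <- list(x_px = x, y_px = y, raw = mean(sub[ap]),
              background = mean(sub[ann]),
              corrected = mean(sub[ap]) - mean(sub[ann]))
  class(out) <- "focus_measurement"
  out
}

#' Measure a set of foci on one plane
#'
#' Applies [measure_focus()] to every point, excluding all other points'
#' apertures from each background annulus.
#'
#' @inheritParams measure_focus
#' @param points Matrix/data.frame with columns `x_px`, `y_px` (or `x`, `y`).
#' @return data.frame: `x_px`, `y_px`, `raw`, `background`, `corrected`.
#' @export
measure_foci <- function(plane, points, pixel_size, aperture_radius = 0.4,
                         bg_inner = 0.5, bg_outer = 0.8) {
  points <- as.data.frame(points)
  xc <- intersect(c("x_px", "x"), names(points))[1]
  yc <- intersect(c("y_px", "y"), names(points))[1]
  if (is.na(xc) || is.na(yc)) stop("points needs x_px/y_px (or x/y) columns")
  pts <- cbind(points[[xc]], points[[yc]])
  do.call(rbind, lapply(seq_len(nrow(pts)), function(i) {
    m <- measure_focus(plane, pts[i, ], pixel_size, aperture_radius,
                       bg_inner, bg_outer,
                       other_points = pts[-i, , drop = FALSE])
    data.frame(x_px = m$x_px, y_px = m$y_px, raw = m$raw,
               background = m$background, corrected = m$corrected)
  }))
}

#' Normalize corrected focus intensities to a reference set
#'
#' Each corrected intensity is divided by the mean corrected intensity of
#' the reference measurements (e.g. GFP-negative cells, or the wild type),
#' so the reference set normalizes to mean 1.0.
#'
#' @param measurements data.frame with a `corrected` column.
#' @param reference_measurements Nonempty data.frame with a `corrected`
#'   column whose mean is positive.
#' @return `measurements` with a `normalized` column appended.
#' @export
normalize_foci <- function(measurements, reference_measurements) {
  if (is.null(reference_measurements) || !nrow(reference_measurements))
    stop("empty reference set")
  ref_mean <- mean(reference_measurements$corrected)
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("reference mean corrected intensity must be positive")
  measurements$normalized <- measurements$corrected / ref_mean
  measurements
}

#' Immunoblot band intensity ratio
#'
#' @param target_band Numeric vector of target band intensities.
#' @param loading_band Matching vector of loading/normalizer band
#'   intensities (> 0).
#' @return For length-1 input, the ratio. For replicates, a list with
#'   `ratios`, `mean`, and `sem`.
#' @export
blot_ratio <- function(target_band, loading_band) {
  if (length(target_band) != length(loading_band))
    stop("target and loading vectors must have equal length")
  if (any(loading_band <= 0)) stop("loading band intensities must be positive")
  r <- target_band / loading_band
  if (length(r) == 1L) return(unname(r))
  list(ratios = r, mean = mean(r), sem = stats::sd(r) / sqrt(length(r)))
}
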
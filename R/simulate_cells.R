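#' Simulate a multichannel immunofluorescence cell field
#'
#' Draws `n_cells` cells as concentric nucleus/cell disks on a grid. The
#' DAPI channel is bright in the nucleus; signal channels (e.g. dynein,
#' KASH5) have a cytoplasmic mean of `channel_means[ch]` and a perinuclear
#' band (1 um half-width around the nuclear boundary) whose mean is
#' `enrichment_factors[ch]` times the cytoplasmic mean. A `sun1` channel can
#' be given its own mean per cell via `channel_means` to exercise inclusion
#' filters. Ground truth records every region mean.
#'
#' @param config A [sim_config()]; `background_sd` sets the additive noise
#'   (0 gives noiseless images), `background_mean` the off-cell background.
#' @param n_cells Number of cells (>= 1).
#' @param enrichment_factors Named numeric, nuclear-envelope enrichment per
#'   signal channel (>= 0), e.g. `c(dynein = 2, kash5 = 3)`.
#' @param channel_means Named numeric or named list of per-cell numeric
#'   vectors: cytoplasmic mean intensity per channel.
#' @param nucleus_radius_um,cell_radius_um Disk radii in um.
#' @param band_halfwidth_um Half-width of the perinuclear band in um.
#' @return List with `channels` (named list of H x W matrices, always
#'   including `dapi`), `masks` (per-cell nucleus and cell binary masks),
#'   `pixel_size`, and `truth` (data.frame: one row per cell per channel
#'   with true region means and the enrichment factor).
#' @export
simulate_cell_field <- function(config, n_cells, enrichment_factors,
                                channel_means,
                                nucleus_radius_um = 7, cell_radius_um = 14,
                                band_halfwidth_um = 1) {
  config <- validate_sim_config(config)
  if (n_cells < 1L) stop("n_cells must be >= 1")
  if (any(enrichment_factors < 0)) stop("enrichment factors must be >= 0")
  set.seed(config$seed)
  px <- config$pixel_size
  r_nuc <- nucleus_radius_um / px
  r_cell <- cell_radius_um / px
  pitch <- ceiling(2.2 * r_cell)
  ncol_grid <- ceiling(sqrt(n_cells))
  nrow_grid <- ceiling(n_cells / ncol_grid)
  h <- as.integer(nrow_grid * pitch); w <- as.integer(ncol_grid * pitch)
  if (h < 2 * r_cell || w < 2 * r_cell) stop("field too small for the cell radius")

  centers <- t(vapply(seq_len(n_cells) - 1L, function(i) {
    c(x = (i %% ncol_grid + 0.5) * pitch, y = (i %/% ncol_grid + 0.5) * pitch)
  }, numeric(2)))

  # normalize channel_means to a list of per-cell vectors
  ch_names <- union(names(channel_means), names(enrichment_factors))
  per_cell <- lapply(ch_names, function(ch) {
    v <- if (is.list(channel_means)) channel_means[[ch]] else channel_means[[ch]]
    if (is.null(v)) v <- 0
    rep_len(v, n_cells)
  })
  names(per_cell) <- ch_names

  xg <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  yg <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)

  channels <- list(dapi = matrix(config$background_mean, h, w))
  for (ch in ch_names) channels[[ch]] <- matrix(config$background_mean, h, w)

  masks <- vector("list", n_cells)
  truth <- list()
  for (i in seq_len(n_cells)) {
    d <- sqrt((xg - centers[i, "x"])^2 + (yg - centers[i, "y"])^2)
    nuc <- d <= r_nuc
    cell <- d <= r_cell
    # band/cytoplasm painted with the same mask algebra the measurement
    # uses, so the noiseless NE:cyto ratio equals the enrichment exactly
    band <- ne_band(nuc, band_halfwidth_um, px)
    masks[[i]] <- list(nucleus = nuc, cell = cell)
    channels$dapi[nuc] <- 1000
    for (ch in ch_names) {
      cm <- per_cell[[ch]][i]
      ef <- if (ch %in% names(enrichment_factors)) enrichment_factors[[ch]] else 1
      plane <- channels[[ch]]
      plane[cell] <- cm
      plane[band] <- ef * cm
      channels[[ch]] <- plane
      truth[[length(truth) + 1L]] <- data.frame(
        cell = i, channel = ch, cyto_mean = cm, ne_mean = ef * cm,
        whole_cell_mean = mean(plane[cell]), enrichment = ef)
    }
  }
  if (config$background_sd > 0)
    for (ch in names(channels))
      channels[[ch]] <- channels[[ch]] +
        matrix(stats::rnorm(h * w, 0, config$background_sd), h, w)

  list(channels = channels, masks = masks, pixel_size = px,
       centers = centers, truth = do.call(rbind, truth))
}

#' Simulate a spermatocyte chromosome spread
#'
#' Each cell carries `n_foci_per_cell / 2` curvilinear synaptonemal-complex
#' axes (SYCP3 channel); telomeric foci sit at both axis endpoints in the
#' `p150` channel over a smooth, spatially varying background. Cells are
#' either GFP-positive "mutant" cells, whose focus amplitude is
#' `focus_fraction_of_reference` times the reference amplitude, or
#' GFP-negative reference cells carrying the full reference amplitude.
#'
#' @param config A [sim_config()]; `spot_amplitude` is the reference focus
#'   amplitude, `psf_sigma` the focus width, `background_sd` the pixel noise.
#' @param n_cells Number of GFP-positive (mutant) cells.
#' @param n_foci_per_cell Foci per cell; must be even (two ends per axis).
#' @param focus_fraction_of_reference Mutant amplitude as a fraction of the
#'   reference amplitude (>= 0).
#' @param n_reference_cells GFP-negative cells carrying reference amplitude.
#' @param cell_size_px Side of the square tile allotted to one cell.
#' @param min_focus_separation_um Minimum separation between foci; violating
#'   axes are resampled.
#' @return List with `cells`: per cell, `channels` (`sycp3`, `p150`),
#'   `traces` (list of [axis_trace()]), `gfp_positive`, `pixel_size`; and
#'   `truth`: data.frame with one row per focus (cell, focus id, x, y, true
#'   amplitude, true local background).
#' @export
simulate_spermatocyte_spread <- function(config, n_cells, n_foci_per_cell,
                                         focus_fraction_of_reference,
                                         n_reference_cells = n_cells,
                                         cell_size_px = 160L,
                                         min_focus_separation_um = 1.8) {
  config <- validate_sim_config(config)
  if (n_foci_per_cell %% 2L != 0L) stop("n_foci_per_cell must be even (two ends per axis)")
  if (focus_fraction_of_reference < 0) stop("focus fraction must be >= 0")
  set.seed(config$seed)
  px <- config$pixel_size
  n_axes <- n_foci_per_cell %/% 2L
  sep_px <- min_focus_separation_um / px
  total <- n_cells + n_reference_cells
  gfp <- c(rep(TRUE, n_cells), rep(FALSE, n_reference_cells))
  cells <- vector("list", total)
  truth <- list()
  for (ci in seq_len(total)) {
    amp <- config$spot_amplitude *
      (if (gfp[ci]) focus_fraction_of_reference else 1)
    cell <- simulate_spread_cell(config, n_axes, amp, cell_size_px, sep_px)
    cell$gfp_positive <- gfp[ci]
    cells[[ci]] <- cell
    tr <- cell$focus_truth
    tr$cell <- ci
    tr$gfp_positive <- gfp[ci]
    truth[[ci]] <- tr
  }
  list(cells = cells, pixel_size = px, truth = do.call(rbind, truth),
       config = config)
}

# One spread cell: axes as quadratic bezier-ish curves, foci at endpoints.
simulate_spread_cell <- function(config, n_axes, amplitude, size, sep_px) {
  h <- w <- as.integer(size)
  px <- config$pixel_size
  sigma_px <- config$psf_sigma / px
  margin <- 12
  # resample until all 2*n_axes endpoints are mutually separated
  for (attempt in 1:200) {
    traces <- lapply(seq_len(n_axes), function(a) {
      p0 <- stats::runif(2, margin, size - margin)
      ang <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, 0.25, 0.45) * size
      p1 <- p0 + len * c(cos(ang), sin(ang))
      p1 <- pmin(pmax(p1, margin), size - margin)
      mid <- (p0 + p1) / 2 + stats::rnorm(2, 0, 0.08 * len)
      tt <- seq(0, 1, length.out = 25)
      verts <- cbind((1 - tt)^2 %o% p0[1] + 2 * tt * (1 - tt) %o% mid[1] + tt^2 %o% p1[1],
                     (1 - tt)^2 %o% p0[2] + 2 * tt * (1 - tt) %o% mid[2] + tt^2 %o% p1[2])
      axis_trace(sprintf("axis%02d", a), verts)
    })
    ends <- do.call(rbind, lapply(traces, function(tr) tr$endpoints))
    if (n_axes == 1L || min(stats::dist(ends)) >= sep_px) break
  }
  if (attempt == 200 && n_axes > 1L && min(stats::dist(ends)) < sep_px)
    stop("could not place foci at the requested separation")

  # smooth spatially varying background: plane gradient + broad Gaussian
  xg <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  yg <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  bg0 <- config$background_mean
  bg <- bg0 * (1 + 0.15 * xg / w - 0.1 * yg / h) +
    0.3 * bg0 * exp(-((xg - w / 2)^2 + (yg - h / 2)^2) / (2 * (w / 2.5)^2))

  sycp3 <- bg
  p150 <- bg
  for (tr in traces) {
    pts <- tr$vertices
    for (k in seq_len(nrow(pts)))
      sycp3 <- add_gaussian_spot(sycp3, pts[k, 1], pts[k, 2], 600, 1.5)
  }
  truth <- list()
  for (tr in traces) {
    for (e in 1:2) {
      pt <- tr$endpoints[e, ]
      local_bg <- bg[round(pt[2]) + 1L, round(pt[1]) + 1L]
      p150 <- add_gaussian_spot(p150, pt[1], pt[2], amplitude, sigma_px)
      truth[[length(truth) + 1L]] <- data.frame(
        axis_id = tr$id, end = e, x_px = pt[1], y_px = pt[2],
        amplitude = amplitude, local_background = local_bg)
    }
  }
  if (config$background_sd > 0) {
    sycp3 <- sycp3 + matrix(stats::rnorm(h * w, 0, config$background_sd), h, w)
    p150 <- p150 + matrix(stats::rnorm(h * w, 0, config$background_sd), h, w)
  }
  list(channels = list(sycp3 = sycp3, p150 = p150), traces = traces,
       focus_truth = do.call(rbind, truth))
}
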
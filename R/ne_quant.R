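#' Maximum-intensity projection of a z-stack
#'
#' @param zstack Array `H x W x Z` or list of equally sized matrices.
#' @return A single `H x W` plane, the pixelwise maximum across z.
#' @export
project_stack <- function(zstack) {
  if (is.list(zstack)) {
    if (!length(zstack)) stop("empty stack")
    out <- zstack[[1]]
    for (p in zstack[-1]) out <- pmax(out, p)
    return(out)
  }
  d <- dim(zstack)
  if (length(d) == 2L) return(zstack)
  if (length(d) != 3L || d[3] < 1L) stop("empty stack")
  apply(zstack, c(1, 2), max)
}

#' Segment nuclei from a DAPI plane
#'
#' Thresholds the plane (Otsu by default), fills holes, labels connected
#' components, and drops components below `min_size` pixels.
#'
#' @param dapi_plane Numeric matrix; must not be constant.
#' @param threshold Absolute intensity threshold; `NULL` uses Otsu on the
#'   rescaled plane.
#' @param min_size Minimum component area in pixels.
#' @return Integer label matrix (0 = background, 1..n = nuclei).
#' @export
segment_nucleus <- function(dapi_plane, threshold = NULL, min_size = 50L) {
  rng <- range(dapi_plane)
  if (diff(rng) == 0) stop("no nucleus: plane is constant")
  if (is.null(threshold)) {
    scaled <- (dapi_plane - rng[1]) / diff(rng)
    threshold <- rng[1] + EBImage::otsu(EBImage::Image(scaled)) * diff(rng)
  }
  mask <- dapi_plane > threshold
  if (!any(mask)) stop("no nucleus: nothing above threshold")
  img <- EBImage::fillHull(EBImage::Image(mask * 1))
  lab <- EBImage::bwlabel(img)
  labm <- EBImage::imageData(lab)
  sizes <- tabulate(labm[labm > 0])
  keep <- which(sizes >= min_size)
  if (!length(keep)) stop("no nucleus: all components below min_size")
  out <- matrix(0L, nrow(dapi_plane), ncol(dapi_plane))
  for (i in seq_along(keep)) out[labm == keep[i]] <- i
  out
}

# disk structuring element with radius r px (odd-sized brush)
disk_brush <- function(r_px) EBImage::makeBrush(2L * as.integer(r_px) + 1L, shape = "disc")

#' Nuclear-envelope band mask
#'
#' The band extends `band_halfwidth` um on either side of the nuclear ROI
#' boundary: `dilate(nucleus, r) XOR erode(nucleus, r)` with a disk of
#' radius `r = band_halfwidth / pixel_size` pixels.
#'
#' @param nucleus_mask Logical (or 0/1) matrix, nonempty.
#' @param band_halfwidth Half-width in um.
#' @param pixel_size um/pixel.
#' @return Logical band mask (empty for `band_halfwidth` 0).
#' @export
ne_band <- function(nucleus_mask, band_halfwidth, pixel_size) {
  nucleus_mask <- nucleus_mask > 0
  if (!any(nucleus_mask)) stop("empty nucleus mask")
  r <- round(band_halfwidth / pixel_size)
  if (r < 1) return(nucleus_mask & FALSE)
  kern <- disk_brush(r)
  img <- EBImage::Image(nucleus_mask * 1)
  dil <- EBImage::imageData(EBImage::dilate(img, kern)) > 0
  ero <- EBImage::imageData(EBImage::erode(img, kern)) > 0
  if (!any(ero)) stop("nucleus smaller than the erosion radius")
  dil & !ero
}

#' Cytoplasm region mask
#'
#' The cell mask minus the nucleus dilated by `margin` um, so the region is
#' disjoint from the NE band's outer edge and the nucleus.
#'
#' @param cell_mask,nucleus_mask Logical matrices of equal size.
#' @param margin Expansion of the nuclear ROI in um.
#' @param pixel_size um/pixel.
#' @return Logical cytoplasm mask.
#' @export
cytoplasm_region <- function(cell_mask, nucleus_mask, margin, pixel_size) {
  cell_mask <- cell_mask > 0; nucleus_mask <- nucleus_mask > 0
  if (!all(dim(cell_mask) == dim(nucleus_mask))) stop("masks must be aligned")
  r <- round(margin / pixel_size)
  grown <- if (r < 1) nucleus_mask else {
    EBImage::imageData(EBImage::dilate(EBImage::Image(nucleus_mask * 1), disk_brush(r))) > 0
  }
  cyto <- cell_mask & !grown
  if (!any(cyto)) stop("empty cytoplasm after subtracting the expanded nucleus")
  cyto
}

#' Measure one cell's region means, NE:cytoplasm ratios, and inclusion
#'
#' @param channels Named list of intensity planes (max projections).
#' @param nucleus_mask,cell_mask Logical masks for this cell.
#' @param pixel_size um/pixel.
#' @param condition One of `"untransfected"`, `"SUN1-only"`, `"KASH5-dTM"`,
#'   `"KASH5-FL"` (full-length or point mutant); drives the inclusion rules.
#' @param band_halfwidth NE band half-width in um (default 1).
#' @param margin Nuclear expansion subtracted from the cytoplasm, um
#'   (default 1).
#' @return Object of class `cell_measurement`: `channels` data.frame
#'   (channel, ne_mean, cyto_mean, whole_cell_mean, ne_cyto_ratio),
#'   `included`, `reason`, `condition`.
#' @export
measure_cell <- function(channels, nucleus_mask, cell_mask, pixel_size,
                         condition, band_halfwidth = 1, margin = 1) {
  band <- ne_band(nucleus_mask, band_halfwidth, pixel_size)
  cyto <- cytoplasm_region(cell_mask, nucleus_mask, margin, pixel_size)
  cellm <- cell_mask > 0
  df <- do.call(rbind, lapply(names(channels), function(ch) {
    p <- channels[[ch]]
    nm <- mean(p[band]); cm <- mean(p[cyto])
    data.frame(channel = ch, ne_mean = nm, cyto_mean = cm,
               whole_cell_mean = mean(p[cellm]), ne_cyto_ratio = nm / cm)
  }))
  meas <- list(channels = df, condition = condition,
               included = NA, reason = "")
  class(meas) <- "cell_measurement"
  apply_inclusion_filters(meas, condition)
}

#' Apply the gray-value inclusion filters for a transfection condition
#'
#' Rules (raw mean gray values, strict "less than" excludes):
#' full-length/mutant KASH5 cells are excluded if the whole-cell KASH5 mean
#' is below 250; SUN1-only and KASH5-dTM cells are excluded if the SUN1
#' mean is below 200; KASH5-dTM cells additionally require a whole-cell
#' KASH5 mean of at least 220. Untransfected cells are always included.
#'
#' @param meas A `cell_measurement`.
#' @param condition Condition tag (see [measure_cell()]).
#' @return The measurement with `included` and `reason` set.
#' @export
apply_inclusion_filters <- function(meas, condition = meas$condition) {
  get_mean <- function(ch) {
    row <- meas$channels[meas$channels$channel == ch, ]
    if (!nrow(row)) stop("missing channel '", ch, "' required by condition ", condition)
    row$whole_cell_mean[1]
  }
  meas$condition <- condition
  meas$included <- TRUE; meas$reason <- ""
  if (condition == "untransfected") {
    return(meas)
  } else if (condition == "KASH5-FL") {
    if (get_mean("kash5") < 250) {
      meas$included <- FALSE; meas$reason <- "KASH5<250"
    }
  } else if (condition == "SUN1-only") {
    if (get_mean("sun1") < 200) {
      meas$included <- FALSE; meas$reason <- "SUN1<200"
    }
  } else if (condition == "KASH5-dTM") {
    if (get_mean("sun1") < 200) {
      meas$included <- FALSE; meas$reason <- "SUN1<200"
    } else if (get_mean("kash5") < 220) {
      meas$included <- FALSE; meas$reason <- "KASH5 whole-cell<220"
    }
  } else {
    stop("unknown condition tag: ", condition)
  }
  meas
}

#' @export
print.cell_measurement <- function(x, ...) {
  cat("cell_measurement (", x$condition, "): ",
      if (isTRUE(x$included)) "included" else paste0("excluded [", x$reason, "]"),
      "\n", sep = "")
  print(x$channels, row.names = FALSE)
  invisible(x)
}
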
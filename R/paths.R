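#' Microtubule path
#'
#' An ordered polyline in pixel coordinates along which particles move and
#' from which kymographs are extracted.
#'
#' @param id Character identifier.
#' @param vertices Numeric matrix with columns `x`, `y` (pixel coordinates,
#'   0-based continuous; at least 2 rows).
#' @return Object of class `mt_path` with precomputed cumulative arclength
#'   (pixels).
#' @export
mt_path <- function(id, vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2L || ncol(vertices) != 2L)
    stop("a path needs >= 2 vertices with columns (x, y)")
  colnames(vertices) <- c("x", "y")
  seg <- sqrt(rowSums(diff(vertices)^2))
  if (any(seg == 0)) stop("path has zero-length segments")
  p <- list(id = as.character(id), vertices = vertices,
            cumlen_px = c(0, cumsum(seg)))
  class(p) <- "mt_path"
  p
}

#' Path length in microns
#' @param path An `mt_path`.
#' @param pixel_size um/pixel.
#' @return Length in um (sum of segment lengths times pixel size).
#' @export
path_length_um <- function(path, pixel_size) {
  stopifnot(inherits(path, "mt_path"), pixel_size > 0)
  max(path$cumlen_px) * pixel_size
}

# Position (and unit tangent) at arclength s_px along the polyline.
# s_px is clamped to [0, L]. Vectorized over s_px.
path_point_at <- function(path, s_px, tangent = FALSE) {
  cl <- path$cumlen_px
  L <- max(cl)
  s <- pmin(pmax(s_px, 0), L)
  seg <- findInterval(s, cl, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1L), length(cl) - 1L)
  v0 <- path$vertices[seg, , drop = FALSE]
  v1 <- path$vertices[seg + 1L, , drop = FALSE]
  seglen <- cl[seg + 1L] - cl[seg]
  f <- (s - cl[seg]) / seglen
  pos <- v0 + (v1 - v0) * f
  if (!tangent) return(pos)
  tg <- (v1 - v0) / seglen
  list(position = pos, tangent = tg)
}

#' Read microtubule paths from a polyline CSV
#'
#' Expected columns: `path_id`, `vertex_index`, `x_px`, `y_px`.
#' @param file CSV file path.
#' @return List of `mt_path`.
#' @export
read_paths_csv <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("path_id", "vertex_index", "x_px", "y_px")
  if (!all(need %in% names(df))) stop("path CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$path_id), function(d) {
    d <- d[order(d$vertex_index), ]
    mt_path(d$path_id[1], cbind(d$x_px, d$y_px))
  })
}

#' Write microtubule paths to a polyline CSV
#' @param paths List of `mt_path`.
#' @param file Output CSV file.
#' @export
write_paths_csv <- function(paths, file) {
  rows <- do.call(rbind, lapply(paths, function(p)
    data.frame(path_id = p$id, vertex_index = seq_len(nrow(p$vertices)) - 1L,
               x_px = p$vertices[, "x"], y_px = p$vertices[, "y"])))
  utils::write.csv(rows, file, row.names = FALSE)
  invisible(file)
}
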
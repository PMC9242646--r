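# Shared builders for synthetic fixtures; everything is generated in code.

# Small fast TIRF configuration for generator tests.
tiny_tirf_config <- function(seed = 1L, movie_duration = 30, ...) {
  sim_config(seed = seed, field_size = c(64L, 140L),
             movie_duration = movie_duration,
             background_mean = 200, background_sd = 15, spot_amplitude = 900,
             ...)
}

# n horizontal paths of the given pixel length, vertically spaced.
straight_paths <- function(n, length_px = 125, x0 = 5, y0 = 6, spacing = 6) {
  lapply(seq_len(n), function(i)
    mt_path(sprintf("p%02d", i),
            cbind(c(x0, x0 + length_px), rep(y0 + (i - 1) * spacing, 2))))
}

# Deterministic single-particle movie built directly (independent of the
# stochastic generator): one emitter moving at `speed` um/s along a
# horizontal path. Returns the movie, the path, and the true arclength
# positions (um per frame).
single_particle_movie <- function(speed = 0.5, n_frames = 40, pixel_size = 0.16,
                                  frame_interval = 0.3, start_um = 1.0,
                                  amplitude = 800, background = 100,
                                  noise_sd = 0, y = 12, height = 24,
                                  length_px = 150, seed = 99L) {
  set.seed(seed)
  width <- length_px + 10
  frames <- array(background, dim = c(height, width, n_frames))
  if (noise_sd > 0)
    frames <- frames + array(rnorm(length(frames), 0, noise_sd), dim(frames))
  sigma_px <- 0.13 / pixel_size
  pos_um <- start_um + speed * frame_interval * (seq_len(n_frames) - 1)
  for (t in seq_len(n_frames)) {
    x <- 5 + pos_um[t] / pixel_size
    frames[, , t] <- adaptorquant:::add_gaussian_spot(frames[, , t], x, y,
                                                      amplitude, sigma_px)
  }
  list(movie = movie_stack(frames, pixel_size, frame_interval, "oracle"),
       path = mt_path("p1", cbind(c(5, 5 + length_px), c(y, y))),
       true_positions_um = pos_um)
}

# Build a bare motility_event from a position trace (um per frame).
make_event <- function(positions, start_frame = 0L, intensity = 100,
                       path_id = "p", censored = FALSE) {
  ev <- list(path_id = path_id, start_frame = as.integer(start_frame),
             end_frame = as.integer(start_frame + length(positions) - 1L),
             positions = positions, mean_spot_intensity = intensity,
             censored = censored, class = NA_character_)
  class(ev) <- "motility_event"
  ev
}

# Binary disk mask on an h x w field, radius in pixels, 0-based center.
disk_mask <- function(h, w, cx, cy, r) {
  xg <- matrix(rep(seq_len(w) - 1, each = h), nrow = h)
  yg <- matrix(rep(seq_len(h) - 1, times = w), nrow = h)
  (xg - cx)^2 + (yg - cy)^2 <= r^2
}

# Minimal cell_measurement for inclusion-filter tests.
make_measurement <- function(whole_means, condition = "KASH5-FL") {
  df <- data.frame(channel = names(whole_means), ne_mean = NA_real_,
                   cyto_mean = NA_real_,
                   whole_cell_mean = unname(whole_means),
                   ne_cyto_ratio = NA_real_)
  m <- list(channels = df, condition = condition, included = NA, reason = "")
  class(m) <- "cell_measurement"
  m
}

# Simulate a velocity-benchmark movie: processive-only traffic at the given
# median speed, analyzed with the full kymograph pipeline.
velocity_benchmark <- function(median_speed, frame_interval, seed) {
  cfg <- sim_config(seed = seed, frame_interval = frame_interval,
                    movie_duration = 180, field_size = c(220L, 320L),
                    landing_rate_true = 0.25,
                    state_fractions = c(1, 0, 0),
                    speed_distribution = list(family = "normal",
                                              location = median_speed,
                                              scale = 0.1 * median_speed),
                    run_length_mean = 3)
  paths <- lapply(1:10, function(i)
    mt_path(sprintf("p%02d", i), cbind(c(10, 310), rep(i * 20, 2))))
  sim <- simulate_tirf_movie(cfg, paths)
  res <- analyze_tirf_movie(sim$movie, paths)
  list(sim = sim, result = res)
}

# Simulate the spermatocyte benchmark (mutant fraction of reference) and
# run the foci pipeline; returns mean normalized mutant intensity.
foci_benchmark <- function(fraction, seed, n_cells = 7, n_foci = 20) {
  cfg <- sim_config(seed = seed, background_mean = 100, background_sd = 8,
                    spot_amplitude = 1200, psf_sigma = 0.15)
  sp <- simulate_spermatocyte_spread(cfg, n_cells = n_cells,
                                     n_foci_per_cell = n_foci,
                                     focus_fraction_of_reference = fraction)
  mut <- list(); ref <- list()
  for (cell in sp$cells) {
    pts <- detect_axis_endpoints(cell$traces)
    m <- measure_foci(cell$channels$p150, pts, sp$pixel_size)
    if (cell$gfp_positive) mut[[length(mut) + 1L]] <- m
    else ref[[length(ref) + 1L]] <- m
  }
  mut <- do.call(rbind, mut); ref <- do.call(rbind, ref)
  norm <- normalize_foci(mut, ref)
  list(mean_normalized = mean(norm$normalized), n_mutant_foci = nrow(mut))
}
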
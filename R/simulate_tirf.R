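#' Simulate a single-molecule TIRF motility movie
#'
#' Particles land on microtubule paths as a Poisson process at
#' `landing_rate_true` events per um per minute, draw a behavioural class
#' from `state_fractions`, and are rendered as Gaussian spots over Gaussian
#' camera background. Processive particles advance along the path at a
#' per-event speed until their exponential run length (or the movie, or the
#' path end) terminates the run; diffusive particles perform a 1-D random
#' walk along the path with reflecting ends; immotile particles hold
#' position. Aggregates are rendered with a multiplied amplitude.
#'
#' @param config A [sim_config()].
#' @param paths List of [mt_path()] lying inside the field.
#' @return List with elements `movie` (a `movie_stack`) and `truth`, a list
#'   holding `events` (one row per landed particle: id, path, frames, class,
#'   true speed, realized run length, aggregate flag) and a `config` echo.
#' @export
simulate_tirf_movie <- function(config, paths) {
  config <- validate_sim_config(config)
  if (length(paths) == 0L) stop("empty path list")
  h <- config$field_size[1]; w <- config$field_size[2]
  for (p in paths) {
    v <- p$vertices
    if (any(v[, "x"] < 0 | v[, "x"] > w - 1 | v[, "y"] < 0 | v[, "y"] > h - 1))
      stop("path ", p$id, " exits the field")
  }
  set.seed(config$seed)
  T <- as.integer(round(config$movie_duration / config$frame_interval))
  if (T < 2L) stop("movie too short for the frame interval")
  dt <- config$frame_interval
  len_um <- vapply(paths, path_length_um, numeric(1), pixel_size = config$pixel_size)
  total_len <- sum(len_um)
  dur_min <- config$movie_duration / 60

  n_events <- stats::rpois(1L, config$landing_rate_true * total_len * dur_min)
  ev <- simulate_event_table(config, paths, len_um, n_events, T)

  # positions per event per frame, in path arclength (um)
  trajectories <- vector("list", n_events)
  if (n_events > 0) for (i in seq_len(n_events)) {
    trajectories[[i]] <- simulate_trajectory(ev[i, ], config, len_um[[ev$path_index[i]]], dt)
    ev$death_frame[i] <- ev$birth_frame[i] + length(trajectories[[i]]) - 1L
    ev$run_length_um[i] <- abs(trajectories[[i]][length(trajectories[[i]])] - trajectories[[i]][1])
  }

  frames <- array(stats::rnorm(h * w * T, config$background_mean, config$background_sd),
                  dim = c(h, w, T))
  sigma_px <- config$psf_sigma / config$pixel_size
  if (n_events > 0) for (i in seq_len(n_events)) {
    traj <- trajectories[[i]]
    amp <- config$spot_amplitude *
      (if (ev$aggregate[i]) config$aggregate_amplitude_multiplier else 1)
    pth <- paths[[ev$path_index[i]]]
    pos <- path_point_at(pth, traj / config$pixel_size)
    for (k in seq_along(traj)) {
      t <- ev$birth_frame[i] + k - 1L
      if (t >= T) break
      frames[, , t + 1L] <- add_gaussian_spot(frames[, , t + 1L],
                                              pos[k, "x"], pos[k, "y"], amp, sigma_px)
    }
  }

  movie <- movie_stack(frames, config$pixel_size, config$frame_interval, "synthetic TIRF")
  truth <- list(events = ev[, c("event_id", "path_id", "birth_frame", "death_frame",
                                "class", "speed_um_s", "run_length_um", "aggregate")],
                trajectories = trajectories, config = config)
  list(movie = movie, truth = truth)
}

# Draw the per-event table (before trajectory realization).
simulate_event_table <- function(config, paths, len_um, n_events, T) {
  if (n_events == 0L) {
    return(data.frame(event_id = integer(0), path_index = integer(0),
                      path_id = character(0), birth_frame = integer(0),
                      death_frame = integer(0), class = character(0),
                      speed_um_s = numeric(0), run_length_draw = numeric(0),
                      run_length_um = numeric(0), start_um = numeric(0),
                      direction = integer(0), dwell_s = numeric(0),
                      aggregate = logical(0)))
  }
  path_index <- sample.int(length(paths), n_events, replace = TRUE, prob = len_um)
  birth <- sample.int(T, n_events, replace = TRUE) - 1L
  cls <- sample(c("processive", "diffusive", "immotile"), n_events,
                replace = TRUE, prob = config$state_fractions)
  sd_ <- config$speed_distribution
  speed <- if (sd_$family == "normal") {
    s <- stats::rnorm(n_events, sd_$location, sd_$scale)
    pmax(s, sd_$location * 0.05)     # truncate away nonphysical negatives
  } else {
    stats::rlnorm(n_events, log(sd_$location), sd_$scale)
  }
  data.frame(event_id = seq_len(n_events), path_index = path_index,
             path_id = vapply(paths, `[[`, character(1), "id")[path_index],
             birth_frame = birth, death_frame = NA_integer_, class = cls,
             speed_um_s = speed,
             run_length_draw = stats::rexp(n_events, 1 / config$run_length_mean),
             run_length_um = NA_real_,
             start_um = stats::runif(n_events) * len_um[path_index],
             direction = sample(c(-1L, 1L), n_events, replace = TRUE),
             dwell_s = stats::rexp(n_events, 1 / config$dwell_time_mean),
             aggregate = stats::runif(n_events) < config$aggregate_fraction)
}

# Arclength (um) per frame from birth until the event ends, >= 1 frame.
simulate_trajectory <- function(ev, config, path_len_um, dt) {
  T <- as.integer(round(config$movie_duration / config$frame_interval))
  max_frames <- T - ev$birth_frame
  bleach_p <- if (config$photobleach_rate > 0) 1 - exp(-config$photobleach_rate * dt) else 0
  s0 <- ev$start_um
  cls <- as.character(ev$class)
  if (cls == "processive") {
    n_run <- ceiling(ev$run_length_draw / (ev$speed_um_s * dt))
    n <- min(max_frames, n_run + 1L)
    s <- s0 + ev$direction * ev$speed_um_s * dt * (seq_len(n) - 1L)
    s <- pmin(pmax(s, 0), path_len_um)
    # stop at path end: truncate after first clamped frame
    hit <- which(s == 0 | s == path_len_um)
    if (length(hit)) s <- s[seq_len(min(hit[1], n))]
  } else if (cls == "diffusive") {
    n <- min(max_frames, max(2L, ceiling(ev$dwell_s / dt)))
    step_sd <- sqrt(2 * config$diffusion_coefficient * dt)
    s <- cumsum(c(s0, stats::rnorm(n - 1L, 0, step_sd)))
    s <- reflect_into(s, 0, path_len_um)
  } else {
    n <- min(max_frames, max(2L, ceiling(ev$dwell_s / dt)))
    s <- rep(s0, n)
  }
  if (bleach_p > 0 && length(s) > 1L) {
    alive <- which(stats::runif(length(s) - 1L) < bleach_p)
    if (length(alive)) s <- s[seq_len(alive[1])]
  }
  s
}

# Reflect values into [lo, hi] (standard folding).
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}
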
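#' Simulation configuration for synthetic TIRF acquisitions
#'
#' Bundles the physical and statistical parameters that the synthetic-data
#' generators share. Defaults mirror a typical single-molecule TIRF setup:
#' EMCCD at 100x (0.16 um/pixel), 300 ms frame interval, 3 min movies, and a
#' diffraction-limited PSF of sigma 0.13 um.
#'
#' @param seed Integer seed; fully determines every generated output.
#' @param pixel_size Pixel size in um/pixel.
#' @param frame_interval Time between frames in seconds (0.3 for purified
#'   protein assays, 0.5 for immunoprecipitate assays).
#' @param movie_duration Total movie length in seconds.
#' @param field_size Integer vector `c(height, width)` in pixels.
#' @param motor_concentration Optional motor concentration in pM, carried
#'   through to landing-rate normalization.
#' @param landing_rate_true True landing rate in events per um of microtubule
#'   per minute.
#' @param state_fractions Length-3 numeric `c(processive, diffusive, immotile)`
#'   proportions; must sum to 1.
#' @param speed_distribution List with elements `family` (`"normal"` or
#'   `"lognormal"`), `location` and `scale`, describing the per-event speed
#'   draw in um/s.
#' @param run_length_mean Mean of the exponential run-length draw in um for
#'   processive events.
#' @param dwell_time_mean Mean dwell time in seconds for diffusive and
#'   immotile events (exponential).
#' @param diffusion_coefficient 1-D diffusion coefficient along the path for
#'   diffusive events, um^2/s.
#' @param psf_sigma Gaussian PSF sigma in um.
#' @param background_mean,background_sd Camera background intensity mean and
#'   Gaussian noise sd (arbitrary units).
#' @param spot_amplitude Peak amplitude of a single fluorophore spot above
#'   background (arbitrary units).
#' @param aggregate_fraction Proportion of landing events that are bright
#'   aggregates.
#' @param aggregate_amplitude_multiplier Amplitude multiplier applied to
#'   aggregate spots.
#' @param photobleach_rate Per-second probability rate of photobleaching
#'   (exponential survival); 0 disables bleaching.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       pixel_size = 0.16,
                       frame_interval = 0.3,
                       movie_duration = 180,
                       field_size = c(128L, 256L),
                       motor_concentration = NULL,
                       landing_rate_true = 0.1,
                       state_fractions = c(processive = 0.7, diffusive = 0.2, immotile = 0.1),
                       speed_distribution = list(family = "normal", location = 0.5, scale = 0.05),
                       run_length_mean = 3,
                       dwell_time_mean = 6,
                       diffusion_coefficient = 0.02,
                       psf_sigma = 0.13,
                       background_mean = 200,
                       background_sd = 20,
                       spot_amplitude = 800,
                       aggregate_fraction = 0,
                       aggregate_amplitude_multiplier = 5,
                       photobleach_rate = 0) {
  cfg <- list(seed = as.integer(seed), pixel_size = pixel_size,
              frame_interval = frame_interval, movie_duration = movie_duration,
              field_size = as.integer(field_size),
              motor_concentration = motor_concentration,
              landing_rate_true = landing_rate_true,
              state_fractions = state_fractions,
              speed_distribution = speed_distribution,
              run_length_mean = run_length_mean,
              dwell_time_mean = dwell_time_mean,
              diffusion_coefficient = diffusion_coefficient,
              psf_sigma = psf_sigma,
              background_mean = background_mean, background_sd = background_sd,
              spot_amplitude = spot_amplitude,
              aggregate_fraction = aggregate_fraction,
              aggregate_amplitude_multiplier = aggregate_amplitude_multiplier,
              photobleach_rate = photobleach_rate)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sf <- cfg$state_fractions
  if (length(sf) != 3L || any(sf < 0) || abs(sum(sf) - 1) > 1e-8)
    stop("state_fractions must be 3 nonnegative proportions summing to 1")
  pos <- c(pixel_size = cfg$pixel_size, frame_interval = cfg$frame_interval,
           movie_duration = cfg$movie_duration, run_length_mean = cfg$run_length_mean,
           dwell_time_mean = cfg$dwell_time_mean, psf_sigma = cfg$psf_sigma,
           spot_amplitude = cfg$spot_amplitude)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("nonphysical config: ", paste(names(pos)[!is.finite(pos) | pos <= 0], collapse = ", "),
         " must be strictly positive")
  if (cfg$landing_rate_true < 0 || cfg$background_sd < 0 || cfg$diffusion_coefficient < 0 ||
      cfg$aggregate_fraction < 0 || cfg$aggregate_fraction > 1 || cfg$photobleach_rate < 0)
    stop("nonphysical config: negative rate or out-of-range proportion")
  if (length(cfg$field_size) != 2L || any(cfg$field_size < 8L))
    stop("field_size must be c(height, width) with both >= 8 pixels")
  if (!cfg$speed_distribution$family %in% c("normal", "lognormal"))
    stop("speed_distribution$family must be 'normal' or 'lognormal'")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$field_size[1], "x", x$field_size[2], "px,",
      x$pixel_size, "um/px,", x$frame_interval, "s/frame,",
      x$movie_duration, "s, seed", x$seed, "\n")
  invisible(x)
}
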
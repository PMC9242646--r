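#' Classification thresholds for motility events
#'
#' The source assays report processive / diffusive / immotile counts without
#' printing numeric criteria; these defaults are plausible for ~0.16 um
#' pixels with sub-pixel centroiding and are all exposed here.
#'
#' @param min_net_displacement Minimum net displacement (um) for a
#'   processive call.
#' @param min_consistency Minimum fraction of frame-to-frame steps sharing
#'   the sign of the net displacement for a processive call.
#' @param immobile_radius Maximum total excursion (um) for an immotile call.
#' @export
classify_params <- function(min_net_displacement = 0.4, min_consistency = 0.7,
                            immobile_radius = 0.2) {
  list(min_net_displacement = min_net_displacement,
       min_consistency = min_consistency, immobile_radius = immobile_radius)
}

#' Classify a motility event
#'
#' Processive iff net displacement >= `min_net_displacement` and the
#' fraction of frame-to-frame steps sharing the net sign >=
#' `min_consistency`; immotile iff the total excursion <= `immobile_radius`;
#' otherwise diffusive.
#'
#' @param event A `motility_event` with >= 2 frames.
#' @param criteria A [classify_params()] list.
#' @return The event with `class` set.
#' @export
classify_event <- function(event, criteria = classify_params()) {
  pos <- event$positions
  if (length(pos) < 2L) stop("cannot classify a single-frame event")
  net <- pos[length(pos)] - pos[1]
  excursion <- max(pos) - min(pos)
  steps <- diff(pos)
  nz <- steps[steps != 0]
  consistency <- if (net == 0 || !length(nz)) 0 else mean(sign(nz) == sign(net))
  event$class <- if (abs(net) >= criteria$min_net_displacement &&
                     consistency >= criteria$min_consistency) {
    "processive"
  } else if (excursion <= criteria$immobile_radius) {
    "immotile"
  } else {
    "diffusive"
  }
  event
}

#' Filter traced events by run length in frames and aggregate brightness
#'
#' Mirrors the analysis rules of the motility assay: runs spanning no more
#' than `min_frames` frames are excluded (with the default 4-frame rule and
#' a 300 ms interval this is a 1.2 s duration threshold), and bright
#' aggregates are excluded as events whose mean spot intensity exceeds
#' `aggregate_multiplier` times the median event intensity of the field.
#'
#' @param events List of `motility_event`.
#' @param min_frames Events whose frame span (number of frames) is `<=`
#'   this value are rejected.
#' @param aggregate_multiplier Intensity multiple of the field median above
#'   which an event is rejected as an aggregate.
#' @return List with `kept` (events) and `rejected` (events, each with a
#'   `reject_reason` of `"too_short"` or `"aggregate"`). `kept` and
#'   `rejected` partition the input.
#' @export
filter_events <- function(events, min_frames = 4L, aggregate_multiplier = 3) {
  if (min_frames < 1L) stop("min_frames must be >= 1")
  if (!length(events)) return(list(kept = list(), rejected = list()))
  span <- vapply(events, function(e) e$end_frame - e$start_frame + 1L, integer(1))
  intens <- vapply(events, function(e) e$mean_spot_intensity, numeric(1))
  med <- stats::median(intens)
  kept <- list(); rejected <- list()
  for (i in seq_along(events)) {
    e <- events[[i]]
    if (span[i] <= min_frames) {
      e$reject_reason <- "too_short"
      rejected[[length(rejected) + 1L]] <- e
    } else if (intens[i] > aggregate_multiplier * med) {
      e$reject_reason <- "aggregate"
      rejected[[length(rejected) + 1L]] <- e
    } else {
      kept[[length(kept) + 1L]] <- e
    }
  }
  list(kept = kept, rejected = rejected)
}

#' Per-event motility metrics
#'
#' Duration is the frame span times the frame interval; run length is the
#' magnitude of the net arclength displacement; velocity is run length over
#' duration. Only defined for processive events.
#'
#' @param event A classified `motility_event` with class `"processive"`.
#' @param frame_interval s/frame.
#' @return List with `duration_s`, `run_length_um`, `velocity_um_s`,
#'   `censored`.
#' @export
event_metrics <- function(event, frame_interval) {
  if (is.na(event$class) || event$class != "processive")
    stop("event_metrics is defined for processive events only")
  duration <- (event$end_frame - event$start_frame) * frame_interval
  run_length <- abs(event$positions[length(event$positions)] - event$positions[1])
  list(duration_s = duration, run_length_um = run_length,
       velocity_um_s = run_length / duration, censored = isTRUE(event$censored))
}

#' Summarize a field of view
#'
#' Landing rate divides the total number of kept events by the summed
#' microtubule length (um) times the movie duration (min), and additionally
#' by the motor concentration (pM) when one is supplied. Percent processive
#' is the processive share of all kept events.
#'
#' @param events Kept, classified events.
#' @param paths List of `mt_path` analyzed in the field.
#' @param movie The source `movie_stack` (for calibration and duration).
#' @param concentration Optional motor concentration in pM.
#' @return List of class `fov_summary`.
#' @export
summarize_fov <- function(events, paths, movie, concentration = NULL) {
  if (!length(paths)) stop("at least one path is required")
  total_len <- sum(vapply(paths, path_length_um, numeric(1),
                          pixel_size = movie$pixel_size))
  if (total_len <= 0) stop("zero total path length")
  dur_min <- movie_duration_min(movie)
  cls <- vapply(events, function(e) e$class, character(1))
  counts <- c(processive = sum(cls == "processive"),
              diffusive = sum(cls == "diffusive"),
              immotile = sum(cls == "immotile"))
  n_total <- length(events)
  lr <- n_total / (total_len * dur_min)
  if (!is.null(concentration)) lr <- lr / concentration
  pp <- if (n_total > 0) 100 * counts[["processive"]] / sum(counts) else NA_real_
  out <- list(counts = counts, total_mt_length_um = total_len,
              movie_duration_min = dur_min,
              motor_concentration_pM = concentration,
              landing_rate = lr, percent_processive = pp)
  class(out) <- "fov_summary"
  out
}

#' @export
print.fov_summary <- function(x, ...) {
  unit <- if (is.null(x$motor_concentration_pM)) "events/um/min"
          else "events/um/min/pM"
  cat(sprintf("FOV: %d events (%d processive, %d diffusive, %d immotile)\n",
              sum(x$counts), x$counts[["processive"]], x$counts[["diffusive"]],
              x$counts[["immotile"]]))
  cat(sprintf("  MT length %.1f um, %.2f min; landing rate %.4g %s; %.1f%% processive\n",
              x$total_mt_length_um, x$movie_duration_min, x$landing_rate, unit,
              x$percent_processive))
  invisible(x)
}

#' Run the full kymograph motility pipeline on a movie
#'
#' Convenience wrapper: for each path, build a kymograph, trace events,
#' classify, and filter; returns per-event metrics for kept processive
#' events plus a field-of-view summary.
#'
#' @param movie A `movie_stack`.
#' @param paths List of `mt_path`.
#' @param width Kymograph transect width (odd pixels).
#' @param detection [detection_params()].
#' @param criteria [classify_params()].
#' @param min_frames,aggregate_multiplier Passed to [filter_events()].
#' @param concentration Optional motor concentration (pM).
#' @return List with `events` (kept classified events), `metrics`
#'   (data.frame of processive-event metrics), `summary` (`fov_summary`),
#'   and `rejected`.
#' @export
analyze_tirf_movie <- function(movie, paths, width = 5L,
                               detection = detection_params(),
                               criteria = classify_params(),
                               min_frames = 4L, aggregate_multiplier = 3,
                               concentration = NULL) {
  all_events <- list()
  for (p in paths) {
    kymo <- build_kymograph(movie, p, width = width)
    evs <- trace_events(kymo, detection)
    all_events <- c(all_events, evs)
  }
  all_events <- lapply(all_events, classify_event, criteria = criteria)
  flt <- filter_events(all_events, min_frames = min_frames,
                       aggregate_multiplier = aggregate_multiplier)
  proc <- Filter(function(e) e$class == "processive", flt$kept)
  metrics <- do.call(rbind, lapply(proc, function(e) {
    m <- event_metrics(e, movie$frame_interval)
    data.frame(path_id = e$path_id, start_frame = e$start_frame,
               end_frame = e$end_frame, duration_s = m$duration_s,
               run_length_um = m$run_length_um, velocity_um_s = m$velocity_um_s,
               censored = m$censored)
  }))
  if (is.null(metrics))
    metrics <- data.frame(path_id = character(0), start_frame = integer(0),
                          end_frame = integer(0), duration_s = numeric(0),
                          run_length_um = numeric(0), velocity_um_s = numeric(0),
                          censored = logical(0))
  list(events = flt$kept, rejected = flt$rejected, metrics = metrics,
       summary = summarize_fov(flt$kept, paths, movie, concentration))
}
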
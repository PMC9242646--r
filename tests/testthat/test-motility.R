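test_that("clear-cut events classify as expected", {
  mono <- classify_event(make_event(seq(0, 3, length.out = 11)))
  expect_identical(mono$class, "processive")
  still <- classify_event(make_event(rep(2.0, 8)))
  expect_identical(still$class, "immotile")
  # symmetric alternation: net 0, excursion above the immobile radius
  wob <- classify_event(make_event(c(0, 0.5, 0, 0.5, 0, 0.5, 0)))
  expect_identical(wob$class, "diffusive")
  expect_error(classify_event(make_event(1.0)), "single-frame")
})

test_that("the frame filter implements the strict four-frame rule", {
  four <- make_event(rep(0, 4))       # spans exactly 4 frames
  five <- make_event(seq(0, 1, length.out = 5))
  out <- filter_events(list(four, five), min_frames = 4)
  expect_length(out$kept, 1)
  expect_length(out$rejected, 1)
  expect_identical(out$rejected[[1]]$reject_reason, "too_short")
  expect_identical(out$kept[[1]]$end_frame, 4L)
  # with the 300 ms interval the kept events last at least 1.2 s
  expect_gte((out$kept[[1]]$end_frame - out$kept[[1]]$start_frame) * 0.3, 1.2)
})

test_that("aggregate exclusion uses the median-intensity rule", {
  evs <- c(lapply(1:9, function(i) make_event(seq(0, 2, length.out = 10),
                                              intensity = 100)),
           list(make_event(seq(0, 2, length.out = 10), intensity = 1000)))
  out <- filter_events(evs, min_frames = 4, aggregate_multiplier = 3)
  expect_length(out$rejected, 1)
  expect_identical(out$rejected[[1]]$reject_reason, "aggregate")
  # equal intensities: nothing rejected as aggregate
  eq <- filter_events(evs[1:9], min_frames = 4, aggregate_multiplier = 3)
  expect_length(eq$rejected, 0)
})

test_that("kept and rejected partition the input without loss", {
  set.seed(1)
  evs <- lapply(1:40, function(i)
    make_event(cumsum(rnorm(sample(2:12, 1), 0.1, 0.2)),
               intensity = exp(rnorm(1, 5, 1))))
  out <- filter_events(evs)
  expect_identical(length(out$kept) + length(out$rejected), 40L)
  key <- function(e) paste(e$start_frame, e$end_frame,
                           signif(e$mean_spot_intensity, 10))
  expect_setequal(c(vapply(out$kept, key, ""), vapply(out$rejected, key, "")),
                  vapply(evs, key, ""))
  empty <- filter_events(list())
  expect_length(empty$kept, 0)
  expect_length(empty$rejected, 0)
})

test_that("event metrics follow the magnitude convention", {
  up <- classify_event(make_event(seq(2, 6, length.out = 11)))   # 10 intervals
  m <- event_metrics(up, frame_interval = 1)
  expect_equal(m$duration_s, 10)
  expect_equal(m$run_length_um, 4)
  expect_equal(m$velocity_um_s, 0.4)
  down <- classify_event(make_event(seq(6, 2, length.out = 11)))
  expect_equal(event_metrics(down, 1)$velocity_um_s, 0.4)
  still <- classify_event(make_event(rep(1, 5)))
  expect_error(event_metrics(still, 1), "processive")
})

test_that("velocity is invariant under path vertex reversal", {
  sp <- single_particle_movie(speed = 0.45, n_frames = 30)
  fwd <- analyze_tirf_movie(sp$movie, list(sp$path))
  rev_path <- mt_path("r", sp$path$vertices[nrow(sp$path$vertices):1, ])
  bwd <- analyze_tirf_movie(sp$movie, list(rev_path))
  expect_equal(nrow(fwd$metrics), 1L)
  expect_equal(nrow(bwd$metrics), 1L)
  expect_equal(fwd$metrics$velocity_um_s, bwd$metrics$velocity_um_s,
               tolerance = 1e-6)
})

test_that("field-of-view summaries implement the landing-rate arithmetic", {
  mv <- movie_stack(array(1, dim = c(24, 200, 600)), 0.16, 0.3)  # 3 min
  paths <- straight_paths(5, length_px = 187.5, y0 = 4, spacing = 4)  # 150 um
  evs <- c(lapply(1:10, function(i) { e <- make_event(1:5); e$class <- "processive"; e }),
           lapply(1:5, function(i) { e <- make_event(rep(1, 5)); e$class <- "immotile"; e }),
           lapply(1:5, function(i) { e <- make_event(c(1, 2, 1, 2, 1)); e$class <- "diffusive"; e }))
  # 30 events would give 0.0667 /um/min/pM; here 20 events
  s <- summarize_fov(evs, paths, mv, concentration = 1)
  expect_equal(s$total_mt_length_um, 150)
  expect_equal(s$movie_duration_min, 3)
  expect_equal(s$landing_rate, 20 / (150 * 3 * 1), tolerance = 1e-12)
  expect_equal(s$percent_processive, 50)
  expect_error(summarize_fov(evs, list(), mv), "path")
})

test_that("pipeline landing rate recovers the simulated rate", {
  cfg <- tiny_tirf_config(seed = 21, landing_rate_true = 0.08,
                          movie_duration = 180,
                          state_fractions = c(1, 0, 0),
                          run_length_mean = 2,
                          speed_distribution = list(family = "normal",
                                                    location = 0.5, scale = 0.05))
  paths <- straight_paths(10, length_px = 125)
  sim <- simulate_tirf_movie(cfg, paths)
  truth_rate <- nrow(sim$truth$events) /
    (sum(vapply(paths, path_length_um, numeric(1), 0.16)) * 3)
  # Poisson SE on the truth count, plus pipeline losses below the 4-frame cut
  se <- sqrt(nrow(sim$truth$events)) / (200 * 3)
  expect_lt(abs(truth_rate - 0.08), 3 * se)
  res <- analyze_tirf_movie(sim$movie, paths)
  expect_gt(length(res$events), 0.5 * nrow(sim$truth$events))
  expect_lte(length(res$events), nrow(sim$truth$events) +
               3 * sqrt(nrow(sim$truth$events)))
})
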
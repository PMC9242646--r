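test_that("cell-field truth equals the configured enrichment", {
  cfg <- sim_config(seed = 4, background_sd = 0, background_mean = 50)
  f1 <- simulate_cell_field(cfg, 2, enrichment_factors = c(dynein = 1.0),
                            channel_means = c(dynein = 300))
  t1 <- f1$truth[f1$truth$channel == "dynein", ]
  expect_equal(t1$ne_mean, t1$cyto_mean)
  f2 <- simulate_cell_field(cfg, 2, enrichment_factors = c(dynein = 2.0),
                            channel_means = c(dynein = 300))
  t2 <- f2$truth[f2$truth$channel == "dynein", ]
  expect_equal(t2$ne_mean / t2$cyto_mean, rep(2, 2))
})

test_that("per-cell channel means pass through to the truth verbatim", {
  set.seed(42)
  kash5_means <- runif(50, 150, 350)
  cfg <- sim_config(seed = 9, background_sd = 0)
  f <- simulate_cell_field(cfg, 50, enrichment_factors = c(kash5 = 1.5),
                           channel_means = list(kash5 = kash5_means))
  tr <- f$truth[f$truth$channel == "kash5", ]
  tr <- tr[order(tr$cell), ]
  expect_equal(tr$cyto_mean, kash5_means)
  for (thr in c(200, 250, 300))
    expect_identical(sum(tr$cyto_mean < thr), sum(kash5_means < thr))
})

test_that("spermatocyte spreads carry one truth row per focus", {
  cfg <- sim_config(seed = 6, background_mean = 100, background_sd = 5,
                    spot_amplitude = 1000, psf_sigma = 0.15)
  sp <- simulate_spermatocyte_spread(cfg, n_cells = 7, n_foci_per_cell = 20,
                                     focus_fraction_of_reference = 0.73,
                                     n_reference_cells = 0)
  expect_identical(nrow(sp$truth), 140L)
  expect_equal(unique(sp$truth$amplitude), 0.73 * 1000)
  expect_error(simulate_spermatocyte_spread(cfg, 1, 7, 1),
               "must be even")
})

test_that("equal and zero focus fractions behave as identities", {
  cfg <- sim_config(seed = 8, background_mean = 100, background_sd = 0,
                    spot_amplitude = 1000, psf_sigma = 0.15)
  sp1 <- simulate_spermatocyte_spread(cfg, 1, 6, 1.0, n_reference_cells = 1)
  amp <- sp1$truth$amplitude
  expect_equal(amp[sp1$truth$gfp_positive], amp[!sp1$truth$gfp_positive])
  sp0 <- simulate_spermatocyte_spread(cfg, 1, 6, 0, n_reference_cells = 0)
  cell <- sp0$cells[[1]]
  m <- measure_foci(cell$channels$p150, detect_axis_endpoints(cell$traces),
                    sp0$pixel_size)
  expect_lt(max(abs(m$corrected)), 2)   # background-gradient residual only
})

test_that("ITC simulation respects trivial limits and determinism", {
  proto <- itc_protocol()
  flat <- simulate_itc(binding_model(N = 1, K_d = 5, dH = 0, baseline = -0.2),
                       proto, noise_sd = 0)
  expect_equal(flat$heats, rep(-0.2, 19))
  a <- simulate_itc(binding_model(N = 0.5, K_d = 4.3, dH = -8), proto,
                    noise_sd = 0.1, seed = 12)
  b <- simulate_itc(binding_model(N = 0.5, K_d = 4.3, dH = -8), proto,
                    noise_sd = 0.1, seed = 12)
  expect_identical(a$heats, b$heats)
})

test_that("stoichiometric-limit cumulative heat matches a step-wise oracle", {
  # K_d -> 0: every injected ligand binds until sites are exhausted.
  # Independent oracle: explicit displacement bookkeeping with min(X, N*M).
  model <- binding_model(N = 1, K_d = 1e-9, dH = -8)
  proto <- itc_protocol()
  heats <- isotherm_heats(model, proto)
  V0 <- proto$cell_volume_ul * 1e-6
  M <- proto$cell_concentration; X <- 0; B_prev <- 0; oracle <- numeric(19)
  for (i in 1:19) {
    dV <- proto$injection_volumes_ul[i] * 1e-6
    f <- 1 - dV / V0
    M <- M * f
    X <- X * f + proto$syringe_concentration * dV / V0
    B <- min(X, M)                       # stoichiometric limit, N = 1
    oracle[i] <- model$dH * 1000 * V0 * (B - B_prev * f)
    B_prev <- B
  }
  expect_equal(heats, oracle, tolerance = 1e-6)
  # closed form N*dH*[cell]0*V0 up to dilution bookkeeping (~10%)
  closed <- model$N * model$dH * 1000 * proto$cell_concentration * V0
  expect_lt(abs(sum(heats) - closed) / abs(closed), 0.10)
})

test_that("MALS traces round-trip and scale linearly", {
  tr <- simulate_mals_trace(100, 0.5, noise_sd = 0)
  expect_equal(mals_mass(tr), 100)
  tr2 <- simulate_mals_trace(100, 1.0, noise_sd = 0)
  expect_equal(tr2$trace$scattering, 2 * tr$trace$scattering)
  expect_error(simulate_mals_trace(0, 1), "positive")
})
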
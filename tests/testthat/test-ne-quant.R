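test_that("max projection equals the brute-force pixel-wise oracle", {
  set.seed(3)
  st <- array(runif(20 * 25 * 3), dim = c(20, 25, 3))
  pr <- project_stack(st)
  oracle <- matrix(0, 20, 25)
  for (i in 1:20) for (j in 1:25) oracle[i, j] <- max(st[i, j, ])
  expect_equal(pr, oracle)
  one <- st[, , 1]
  expect_equal(project_stack(list(one)), one)
  expect_equal(project_stack(list(one, one + 1)), one + 1)
  expect_error(project_stack(list()), "empty")
})

test_that("nucleus segmentation recovers synthetic disks", {
  plane <- matrix(50, 120, 120)
  truth <- disk_mask(120, 120, 40, 60, 20)
  plane[truth] <- 800
  lab <- segment_nucleus(plane)
  expect_identical(max(lab), 1L)
  got <- lab == 1
  iou <- sum(got & truth) / sum(got | truth)
  expect_gte(iou, 0.95)
  # two disks -> two labels
  plane2 <- matrix(50, 120, 120)
  plane2[disk_mask(120, 120, 30, 30, 15)] <- 800
  plane2[disk_mask(120, 120, 90, 90, 15)] <- 800
  expect_identical(max(segment_nucleus(plane2)), 2L)
  expect_error(segment_nucleus(matrix(10, 50, 50)), "no nucleus")
})

test_that("the NE band matches the annulus-area formula", {
  px <- 0.16
  nuc <- disk_mask(220, 220, 110, 110, 10 / px)    # 10 um disk
  band <- ne_band(nuc, 1, px)
  area_um2 <- sum(band) * px^2
  expect_lt(abs(area_um2 - pi * (11^2 - 9^2)) / (pi * (11^2 - 9^2)), 0.05)
  expect_identical(sum(ne_band(nuc, 0, px)), 0L)
  # translation equivariance
  sh <- 7L
  nuc2 <- matrix(FALSE, 220, 220)
  nuc2[(1 + sh):220, ] <- nuc[1:(220 - sh), ]
  band2 <- ne_band(nuc2, 1, px)
  ref <- matrix(FALSE, 220, 220)
  ref[(1 + sh):220, ] <- band[1:(220 - sh), ]
  expect_identical(band2, ref)
  expect_error(ne_band(disk_mask(40, 40, 20, 20, 2), 1, px), "erosion radius")
})

test_that("the cytoplasm region matches the concentric-disk formula", {
  px <- 0.16
  cell <- disk_mask(300, 300, 150, 150, 20 / px)
  nuc <- disk_mask(300, 300, 150, 150, 10 / px)
  cyto <- cytoplasm_region(cell, nuc, 1, px)
  area <- sum(cyto) * px^2
  expected <- pi * (20^2 - 11^2)
  expect_lt(abs(area - expected) / expected, 0.05)
  expect_identical(cytoplasm_region(cell, nuc, 0, px), cell & !nuc)
  expect_error(cytoplasm_region(nuc, nuc, 1, px), "empty cytoplasm")
})

test_that("band, eroded nucleus, and cytoplasm are pairwise disjoint", {
  px <- 0.16
  cell <- disk_mask(300, 300, 150, 150, 18 / px)
  nuc <- disk_mask(300, 300, 150, 150, 9 / px)
  band <- ne_band(nuc, 1, px)
  cyto <- cytoplasm_region(cell, nuc, 1, px)
  r <- round(1 / px)
  interior <- EBImage::imageData(EBImage::erode(EBImage::Image(nuc * 1),
                                                EBImage::makeBrush(2 * r + 1, "disc"))) > 0
  expect_false(any(band & interior))
  expect_false(any(band & cyto))
  expect_false(any(cyto & interior))
  expect_true(all((band | interior | cyto) <= cell | band))
})

test_that("noiseless measured ratios equal the configured enrichment", {
  cfg <- sim_config(seed = 5, background_sd = 0, background_mean = 50)
  f <- simulate_cell_field(cfg, 2, enrichment_factors = c(dynein = 2.0, kash5 = 1.0),
                           channel_means = c(dynein = 300, kash5 = 400, sun1 = 250))
  m <- measure_cell(f$channels[c("dynein", "kash5", "sun1")],
                    f$masks[[1]]$nucleus, f$masks[[1]]$cell, f$pixel_size,
                    condition = "KASH5-FL")
  ch <- m$channels
  expect_equal(ch$ne_cyto_ratio[ch$channel == "dynein"], 2.0)
  expect_equal(ch$ne_cyto_ratio[ch$channel == "kash5"], 1.0)
})

test_that("mean measured ratio recovers the enrichment on a noisy field", {
  cfg <- sim_config(seed = 17, background_sd = 10, background_mean = 50)
  f <- simulate_cell_field(cfg, 50, enrichment_factors = c(dynein = 2.0),
                           channel_means = c(dynein = 300, kash5 = 400, sun1 = 250))
  ratios <- vapply(seq_along(f$masks), function(i) {
    m <- measure_cell(f$channels[c("dynein", "kash5", "sun1")],
                      f$masks[[i]]$nucleus, f$masks[[i]]$cell, f$pixel_size,
                      condition = "KASH5-FL")
    m$channels$ne_cyto_ratio[m$channels$channel == "dynein"]
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 2.0) / 2.0, 0.03)
})

test_that("ratios are gain-invariant but not offset-invariant", {
  cfg <- sim_config(seed = 5, background_sd = 0, background_mean = 50)
  f <- simulate_cell_field(cfg, 1, enrichment_factors = c(dynein = 2.0),
                           channel_means = c(dynein = 300, kash5 = 300, sun1 = 300))
  get_ratio <- function(chs) {
    m <- measure_cell(chs, f$masks[[1]]$nucleus, f$masks[[1]]$cell,
                      f$pixel_size, condition = "KASH5-FL")
    m$channels$ne_cyto_ratio[m$channels$channel == "dynein"]
  }
  chs <- f$channels[c("dynein", "kash5", "sun1")]
  base <- get_ratio(chs)
  gained <- chs; gained$dynein <- 3.7 * gained$dynein
  expect_equal(get_ratio(gained), base, tolerance = 1e-12)
  offset <- chs; offset$dynein <- offset$dynein + 100
  expect_false(isTRUE(all.equal(get_ratio(offset), base, tolerance = 1e-6)))
})

test_that("inclusion filters apply the per-condition gray-value rules", {
  m1 <- apply_inclusion_filters(make_measurement(c(kash5 = 240, sun1 = 300)),
                                "KASH5-FL")
  expect_false(m1$included)
  expect_identical(m1$reason, "KASH5<250")
  m2 <- apply_inclusion_filters(make_measurement(c(kash5 = 219, sun1 = 300)),
                                "KASH5-dTM")
  expect_false(m2$included)
  expect_identical(m2$reason, "KASH5 whole-cell<220")
  # strict less-than: boundary values are included
  m3 <- apply_inclusion_filters(make_measurement(c(sun1 = 200)), "SUN1-only")
  expect_true(m3$included)
  m4 <- apply_inclusion_filters(make_measurement(c(kash5 = 250, sun1 = 0)),
                                "KASH5-FL")
  expect_true(m4$included)
  m5 <- apply_inclusion_filters(make_measurement(c(kash5 = 500)), "untransfected")
  expect_true(m5$included)
  expect_error(apply_inclusion_filters(make_measurement(c(kash5 = 1)), "mystery"),
               "unknown condition")
  expect_error(apply_inclusion_filters(make_measurement(c(kash5 = 300)), "SUN1-only"),
               "missing channel")
})
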
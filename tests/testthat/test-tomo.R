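test_that("decay correction recovers -log(flux) offsets from empty margins", {
  sim <- cached("decay_sim",
                simulate_scan(tiny_phantom(), n_angles = 20L, n_rows = 400L,
                              n_cols = 200L, noise = FALSE, decay_to = 0.90,
                              seed = 9))
  av <- averaged(sim)
  reg <- find_beam_region(av$flat, av$dark)
  atts <- lapply(sim$stacks$tomo$frames, normalize_attenuation,
                 dark = av$dark, flat = av$flat)
  dc <- decay_correct(atts, margins = c(20, 20), region = reg)
  expect_lt(max(abs(dc$offsets - (-log(sim$truth$flux_factors)))), 2e-3)
  # post-correction margin means are ~0
  post <- vapply(dc$corrected, function(a)
    mean(a$values[, c(1:20, 181:200)], na.rm = TRUE), 0)
  expect_lt(max(abs(post)), 1e-3)
  expect_error(decay_correct(atts, c(0, 20)), "zero-width")
  expect_error(decay_correct(atts, c(150, 150)), "wider than")
})

test_that("decay correction leaves undecayed data unchanged", {
  sim <- tiny_scan()
  av <- averaged(sim)
  reg <- find_beam_region(av$flat, av$dark)
  atts <- lapply(sim$stacks$tomo$frames, normalize_attenuation,
                 dark = av$dark, flat = av$flat)
  dc <- decay_correct(atts, margins = c(20, 20), region = reg)
  expect_lt(max(abs(dc$offsets)), 1e-6)
  expect_lt(max(abs(dc$corrected[[1]]$values - atts[[1]]$values),
                na.rm = TRUE), 1e-6)
})

test_that("rotation center is found to subpixel for centered/shifted objects", {
  ang <- seq(0, 180, by = 1)
  W <- 128
  centered <- disk_sinogram(W, 20, ang)
  expect_equal(find_center(centered), (W - 1) / 2, tolerance = 0.25)
  shifted <- disk_sinogram(W, 20, ang, shift = 3.0)
  expect_equal(find_center(shifted), (W - 1) / 2 + 3.0, tolerance = 0.25)
  # nearest-pair search works on a 0..179 grid too
  near <- disk_sinogram(W, 20, seq(0, 179, by = 1), shift = 3.0)
  expect_equal(find_center(near), (W - 1) / 2 + 3.0, tolerance = 0.35)
  expect_error(find_center(disk_sinogram(W, 20, 0)), ">= 2 projections")
  expect_error(find_center(disk_sinogram(W, 20, seq(0, 90, by = 1))),
               "angular span")
})

test_that("FBP reconstructs a uniform disk quantitatively", {
  W <- 128; r <- 20
  ang <- seq(0, 179, by = 1)
  sino <- disk_sinogram(W, r, ang, density = 1.0)
  rec <- reconstruct_fbp(sino, pixel_spacing = 1)
  idx <- (0:(W - 1)) - (W - 1) / 2
  rr <- outer(idx^2, idx^2, `+`)
  inside <- rr <= (0.8 * r)^2
  outside <- rr > (1.3 * r)^2 & rr <= (W / 2 - 2)^2
  expect_equal(mean(rec$values[inside]), 1.0, tolerance = 0.02)
  expect_lt(mean(abs(rec$values[outside])), 0.02)
  # pixel-spacing scaling: halving the spacing doubles the density values
  rec2 <- reconstruct_fbp(sino, pixel_spacing = 0.5)
  expect_equal(rec2$values, 2 * rec$values)
  # mass consistency within 3%
  expect_equal(sum(rec$values), mean(rowSums(sino$values)), tolerance = 0.03)
  # all-zero sinogram reconstructs to zero
  z <- sino; z$values[] <- 0
  expect_true(all(reconstruct_fbp(z, pixel_spacing = 1)$values == 0))
  expect_error(reconstruct_fbp(sino, filter_name = "butterworth"),
               "unknown filter")
})

test_that("FBP is linear and windowed filters lower noise, not signal", {
  W <- 96; r <- 15
  ang <- seq(0, 179, by = 2)
  s1 <- disk_sinogram(W, r, ang)
  s2 <- disk_sinogram(W, r, ang, shift = 6)
  ab <- s1; ab$values <- 2 * s1$values + 0.5 * s2$values
  r1 <- reconstruct_fbp(s1, pixel_spacing = 1)
  r2 <- reconstruct_fbp(s2, pixel_spacing = 1)
  rab <- reconstruct_fbp(ab, pixel_spacing = 1)
  expect_lt(max(abs(rab$values - 2 * r1$values - 0.5 * r2$values)),
            1e-6 * max(abs(rab$values)))
  # hann vs ramp on a noisy replicate: same interior mean, lower variance
  set.seed(6)
  noisy <- s1
  noisy$values <- noisy$values + matrix(rnorm(length(noisy$values), sd = 1),
                                        nrow(noisy$values))
  idx <- (0:(W - 1)) - (W - 1) / 2
  inside <- outer(idx^2, idx^2, `+`) <= (0.75 * r)^2
  ramp <- reconstruct_fbp(noisy, pixel_spacing = 1, filter_name = "ramp")
  hann <- reconstruct_fbp(noisy, pixel_spacing = 1, filter_name = "hann")
  expect_equal(mean(hann$values[inside]), mean(ramp$values[inside]),
               tolerance = 0.01)
  expect_lt(var(as.vector(hann$values[inside])),
            var(as.vector(ramp$values[inside])))
  for (fn in c("shepp-logan", "cosine", "hamming")) {
    rf <- reconstruct_fbp(s1, pixel_spacing = 1, filter_name = fn)
    expect_equal(mean(rf$values[inside]), mean(r1$values[inside]),
                 tolerance = 0.02)
  }
})

test_that("decay correction removes the reconstruction artifacts it causes", {
  run <- function(correct) {
    sim <- cached("decay_sim2",
                  simulate_scan(tiny_phantom(), n_angles = 90L,
                                n_rows = 400L, n_cols = 200L, noise = FALSE,
                                decay_to = 0.85, seed = 10))
    av <- averaged(sim)
    reg <- find_beam_region(av$flat, av$dark)
    ana <- analyze_scan(sim$stacks, sim$truth$geometry,
                        references = sim$truth$spectra, mode = "ct",
                        calibration = "one_point",
                        margins = if (correct) c(20, 20),
                        blur_references = FALSE, debias = FALSE)
    rec <- reconstruct_fbp(get_sinogram(ana$maps, "water"),
                           pixel_spacing = 9e-4)
    idx <- ((0:199) - rec$center_used) * 9e-4
    inside <- outer(idx^2, idx^2, `+`) <= (0.5 * 0.06)^2
    sqrt(mean((rec$values[inside] - 1.0)^2))
  }
  rms_raw <- run(FALSE)
  rms_cor <- run(TRUE)
  expect_gt(rms_raw / rms_cor, 3)
})
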
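test_that("flat/dark normalization computes -ln(T) and masks bad pixels", {
  tomo <- matrix(c(60, 110, 10, 5), 2, 2)
  dark <- matrix(10, 2, 2)
  flat <- matrix(c(110, 110, 110, 5), 2, 2)
  att <- normalize_attenuation(tomo, dark, flat)
  expect_equal(att$values[1, 1], -log(50 / 100))
  expect_equal(att$values[1, 1], 0.693147, tolerance = 1e-6)
  expect_equal(att$values[2, 1], 0)              # tomo == flat
  expect_false(att$mask[2, 2])                   # flat - dark <= 0
  expect_true(is.na(att$values[2, 2]))
  expect_error(normalize_attenuation(matrix(1, 2, 2), matrix(5, 2, 2),
                                     matrix(2, 2, 2)), "all pixels masked")
  expect_error(normalize_attenuation(matrix(1, 2, 2), matrix(0, 2, 3),
                                     matrix(2, 2, 3)), "share one shape")
})

test_that("the Poisson log-bias correction centers low-count attenuation", {
  set.seed(31)
  lam <- 60
  n <- 20000
  tomo <- matrix(rpois(n, lam) + 100, 100, 200)
  dark <- matrix(100, 100, 200)
  flat <- matrix(lam * 2 + 100, 100, 200)   # noiseless flat
  plain <- normalize_attenuation(tomo, dark, flat)
  deb <- normalize_attenuation(tomo, dark, flat, debias = TRUE,
                               n_flat_frames = 1e9)
  truth <- -log(lam / (2 * lam))
  expect_gt(abs(mean(plain$values) - truth), 5e-3)   # visible bias ~1/(2*60)
  expect_lt(abs(mean(deb$values) - truth), 2e-3)
})

test_that("beam region finds the Gaussian profile's thresholded run", {
  n_rows <- 200
  sigma <- 20
  prof <- 1000 * exp(-0.5 * ((0:(n_rows - 1)) - 100)^2 / sigma^2)
  flat <- matrix(prof, n_rows, 5)
  flat[, 3] <- 500                       # uniform positive column
  dark <- matrix(0, n_rows, 5)
  reg <- find_beam_region(flat, dark, threshold_fraction = 0.5)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_lt(max(abs((reg$bottom - reg$top)[c(1, 2, 4, 5)] - fwhm)), 1.5)
  expect_equal(reg$top[3], 0L)           # full column retained
  expect_equal(reg$bottom[3], n_rows)
  expect_error(find_beam_region(matrix(0, 10, 3), matrix(0, 10, 3)),
               "beam absent")
  expect_error(find_beam_region(flat, dark, threshold_fraction = 1.2),
               "\\(0, 1\\)")
  # columns shorter than the minimum height are excluded
  flat2 <- flat; flat2[, 2] <- 0; flat2[100, 2] <- 10
  reg2 <- find_beam_region(flat2, dark, 0.5, min_height = 8)
  expect_true(reg2$excluded[2])
})

test_that("edge localization is subpixel-accurate and tracks the bow", {
  att <- edge_attenuation_image(rep(240, 32), n_rows = 400)
  reg <- full_region(400, 32)
  tr <- find_edge(att, reg)
  expect_true(all(tr$valid))
  expect_lt(max(abs(tr$row - 240)), 0.25)
  # quadratic bow across 1024 columns reproduced within 0.5 px RMS
  cols <- 0:1023
  bow <- 240 + 5e-4 * (cols - 512)^2
  att2 <- edge_attenuation_image(bow, n_rows = 400)
  tr2 <- find_edge(att2, full_region(400, 1024))
  expect_lt(sqrt(mean((tr2$row - bow)^2)), 0.5)
  # an edge-free column is flagged invalid
  att3 <- att
  att3$values[, 5] <- 1.0
  tr3 <- find_edge(att3, reg)
  expect_false(tr3$valid[5])
  expect_true(all(tr3$valid[-5]))
  flat_att <- structure(list(values = matrix(1, 50, 3),
                             mask = matrix(TRUE, 50, 3)),
                        class = "attenuation_image")
  expect_error(find_edge(flat_att, full_region(50, 3)), "no valid column")
})

test_that("edge localization is unbiased under Poisson noise", {
  set.seed(17)
  n_rows <- 400
  n_cols <- 200
  prof <- 1e4 * exp(-0.5 * ((0:(n_rows - 1)) - 200)^2 / 51^2)
  mu <- 0.3 + 2 * stats::pnorm(0:(n_rows - 1), 200.3, 1.2)
  lam <- outer(prof, rep(1, n_cols)) * exp(-mu)
  tomo <- matrix(rpois(n_rows * n_cols, lam), n_rows) + 100
  att <- normalize_attenuation(tomo, matrix(100, n_rows, n_cols),
                               outer(prof, rep(1, n_cols)) + 100)
  reg <- find_beam_region(outer(prof, rep(1, n_cols)) + 100,
                          matrix(100, n_rows, n_cols))
  tr <- find_edge(att, reg)
  expect_gt(sum(tr$valid), 190)
  expect_lt(abs(mean(tr$row[tr$valid]) - 200.3), 0.1)
})

test_that("one-point energy map matches the closed form and is monotone", {
  g <- system_geometry(reflection = c(1, 1, 1), edge_energy = 12.658,
                       pixel_size = 0.009, focus_to_detector = 500,
                       energy_direction = -1L)
  tr <- structure(list(row = rep(150, 3), fwhm = rep(2, 3),
                       valid = rep(TRUE, 3), smooth_window = 3L),
                  class = "edge_trace")
  emap <- energy_map_one_point(tr, g, 400)
  # anchor identity
  expect_equal(emap$energies[151, 2], 12.658, tolerance = 1e-12)
  # independent hand evaluation at p - p_K = +100, direction -1
  theta_K <- asin(12.398420 / (2 * (5.431 / sqrt(3)) * 12.658))
  theta <- theta_K - atan(100 * 0.009 / 500)
  expect_equal(emap$energies[251, 1],
               12.398420 / (2 * (5.431 / sqrt(3)) * sin(theta)),
               tolerance = 1e-12)
  # direction -1: energy increases with row; strictly monotone
  expect_true(all(diff(emap$energies[, 1]) > 0))
  g2 <- system_geometry(reflection = c(1, 1, 1), edge_energy = 12.658,
                        pixel_size = 0.009, focus_to_detector = 500)
  emap2 <- energy_map_one_point(tr, g2, 400)
  expect_true(all(diff(emap2$energies[, 1]) < 0))
  # local linearity: dE/dp ~ -E cot(theta_K) pixel/F within 1% at +-20 px
  dEdp_pred <- -12.658 / tan(theta_K) * 0.009 / 500
  p <- 131:171
  dEdp_obs <- diff(emap2$energies[p, 1])
  expect_lt(max(abs(dEdp_obs - dEdp_pred) / abs(dEdp_pred)), 0.01)
})

test_that("two-point energy map reproduces both anchors exactly", {
  g <- default_sim_geometry()
  E1 <- 12.667; E2 <- 12.681
  an <- calibration_anchors(p1 = 194, E1 = E1, p2 = 184, E2 = E2,
                            geometry = g)
  emap <- energy_map_two_point(an, g, 400, n_cols = 1)
  expect_equal(emap$energies[195, 1], E1, tolerance = 1e-10)
  expect_equal(emap$energies[185, 1], E2, tolerance = 1e-10)
  expect_true(all(diff(emap$energies[, 1]) < 0))
  expect_error(calibration_anchors(p1 = 100, E1 = 12.6, p2 = 100,
                                   E2 = 12.7, geometry = g), "degenerate")
  expect_error(calibration_anchors(p1 = 100, E1 = 12.6, p2 = 110,
                                   E2 = 12.6, geometry = g), "degenerate")
})

test_that("two-point calibration recovers the generating energy map", {
  sim <- calib_sim()
  av <- averaged(sim)
  g <- sim$truth$geometry
  reg <- find_beam_region(av$flat, av$dark)
  sa <- normalize_attenuation(average_stack(sim$stacks$edge_speciation),
                              av$dark, av$flat)
  pk <- find_absorption_peaks(sa, reg)
  an <- anchors_from_peaks(pk, c(12.667, 12.681), g)
  emap <- energy_map_two_point(an, g, 400)
  # agreement with the simulator's generating map inside the beam
  err <- numeric(0)
  for (j in seq_len(64)) {
    rows <- (reg$top[j] + 1):reg$bottom[j]
    err <- c(err, emap$energies[rows, j] - sim$truth$emap$energies[rows, j])
  }
  expect_lt(max(abs(err)), 2e-4)
})

test_that("noise-free forward model round-trips through normalization", {
  sim <- tiny_scan()
  av <- averaged(sim)
  att <- normalize_attenuation(sim$stacks$tomo$frames[[1]], av$dark, av$flat)
  cube <- spexim:::mu_cube(sim$truth$spectra, sim$truth$emap)
  A_true <- matrix(0, 400, 200)
  for (m in seq_len(dim(cube)[3]))
    A_true <- A_true + cube[, , m] *
      rep(sim$truth$rho_t[1, , m], each = 400)
  reg <- find_beam_region(av$flat, av$dark)
  sel <- matrix(FALSE, 400, 200)
  for (j in 1:200) sel[(reg$top[j] + 1):reg$bottom[j], j] <- TRUE
  expect_lt(max(abs(att$values[sel] - A_true[sel])), 1e-9)
})

test_that("resolution estimation recovers the edge width and scales", {
  g <- system_geometry(reflection = c(1, 1, 1), edge_energy = 12.658,
                       pixel_size = 0.009, focus_to_detector = 2000)
  run <- function(sigma_E) {
    sim <- simulate_scan(NULL, geometry = g, n_angles = 1L, n_rows = 400L,
                         n_cols = 48L, noise = FALSE, sigma_E = sigma_E,
                         seed = 5)
    av <- averaged(sim)
    reg <- find_beam_region(av$flat, av$dark)
    ea <- normalize_attenuation(average_stack(sim$stacks$edge_elemental),
                                av$dark, av$flat)
    tr <- find_edge(ea, reg)
    estimate_resolution(tr, sim$truth$emap, g)
  }
  w_film <- 4e-4                # intrinsic film edge width (sigma, keV)
  sig1 <- 1.2e-3
  r1 <- run(sig1)
  total1 <- 2 * sqrt(2 * log(2)) * sqrt(sig1^2 + w_film^2) / 12.658
  expect_equal(r1$relative, total1, tolerance = 0.15)
  # doubling the blur doubles the estimate (within 15%)
  r2 <- run(2 * sig1)
  total2 <- 2 * sqrt(2 * log(2)) * sqrt((2 * sig1)^2 + w_film^2) / 12.658
  expect_equal(r2$relative / r1$relative, total2 / total1, tolerance = 0.15)
  # sigma/FWHM/relative bookkeeping
  expect_equal(r1$gaussian_sigma, r1$fwhm_energy / (2 * sqrt(2 * log(2))))
  expect_equal(r1$relative, r1$fwhm_energy / 12.658)
})

test_that("an unblurred ideal step measures at the discretization floor", {
  att <- edge_attenuation_image(rep(120, 16), n_rows = 240, sigma = 1e-6)
  tr <- find_edge(att, full_region(240, 16))
  g <- default_sim_geometry()
  emap <- energy_map_one_point(tr, g, 240)
  res <- estimate_resolution(tr, emap, g)
  expect_true(res$at_floor)
  expect_lt(res$fwhm_pixels, 2)          # ~1-2 px equivalent
  expect_gt(res$fwhm_pixels, 0.5)
})
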
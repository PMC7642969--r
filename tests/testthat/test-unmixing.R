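band <- seq(12.45, 12.85, by = 2e-4)
four_refs <- lapply(c("selenate", "selenite", "selenomethionine", "water"),
                    species_spectrum)

test_that("a noiseless column built from 2 of 4 references is recovered", {
  E <- band
  x_true <- c(selenate = 3e-3, selenite = 0, selenomethionine = 0,
              water = 0.8)
  A <- x_true["selenate"] * resample_to_column(four_refs[[1]], E) +
    x_true["water"] * resample_to_column(four_refs[[4]], E)
  fit <- fit_column(A, E, four_refs)
  expect_lt(max(abs(fit$coefficients - x_true)), 1e-9 * max(x_true))
  expect_lt(fit$residual_rms, 1e-10)
  expect_equal(fit$dof, length(E) - 4)
  # fitted spectrum equals design %*% coefficients
  expect_equal(fit$fitted, A, tolerance = 1e-9)
  # zero attenuation -> all coefficients zero
  z <- fit_column(rep(0, length(E)), E, four_refs)
  expect_equal(unname(z$coefficients), rep(0, 4))
})

test_that("degenerate and underdetermined designs are rejected by name", {
  E <- band
  twice <- list(species_spectrum("selenate"), species_spectrum("selenate"))
  twice[[2]]$name <- "selenate_copy"
  expect_error(fit_column(rep(1, length(E)), E, twice),
               "degenerate reference pair.*selenate.*selenate_copy")
  expect_error(fit_column(rep(1, 3), E[1:3], four_refs),
               "insufficient pixels")
})

test_that("masked pixels are dropped, not imputed", {
  E <- band
  A <- 0.5 * resample_to_column(four_refs[[4]], E)
  A[c(10, 50, 90)] <- NA
  fit <- fit_column(A, E, four_refs)
  expect_equal(unname(fit$coefficients["water"]), 0.5, tolerance = 1e-9)
  expect_equal(fit$n_used, length(E) - 3)
  expect_true(all(is.na(fit$fitted[c(10, 50, 90)])))
})

test_that("non-negative mode matches OLS on interior solutions, clips else", {
  E <- band
  A <- 2e-3 * resample_to_column(four_refs[[1]], E) +
    0.5 * resample_to_column(four_refs[[4]], E)
  f1 <- fit_column(A, E, four_refs, nonneg = FALSE)
  f2 <- fit_column(A, E, four_refs, nonneg = TRUE)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-7)
  # a negative true component gets clipped to zero under the constraint
  An <- A - 1e-3 * resample_to_column(four_refs[[2]], E)
  f3 <- fit_column(An, E, four_refs, nonneg = TRUE)
  expect_true(all(f3$coefficients >= 0))
  expect_equal(unname(f3$coefficients["selenite"]), 0)
})

test_that("coefficients are unbiased under Poisson noise", {
  set.seed(23)
  E <- seq(12.5, 12.82, by = 1.5e-3)   # ~215 pixels
  x_true <- c(selenate = 3e-3, selenite = 2.5e-3,
              selenomethionine = 3.5e-3, water = 0.7)
  X <- vapply(four_refs, resample_to_column, numeric(length(E)),
              column_energies = E)
  A_true <- as.numeric(X %*% x_true)
  flat <- 1e4
  sums <- matrix(0, 500, 4)
  for (i in 1:500) {
    counts <- rpois(length(E), flat * exp(-A_true))
    A <- -log(counts / flat) - 1 / (2 * counts)   # debiased, noiseless flat
    sums[i, ] <- fit_column(A, E, four_refs)$coefficients
  }
  ratio <- colMeans(sums) / x_true
  expect_true(all(ratio > 0.99 & ratio < 1.01))
})

test_that("adding an orthogonal-ish reference leaves true coefficients", {
  E <- band
  A <- 3e-3 * resample_to_column(four_refs[[1]], E) +
    0.8 * resample_to_column(four_refs[[4]], E)
  f2 <- fit_column(A, E, four_refs[c(1, 4)])
  f4 <- fit_column(A, E, four_refs)
  expect_equal(f4$coefficients[c("selenate", "water")],
               f2$coefficients, tolerance = 1e-8)
})

test_that("projection fitting covers retained columns and meets its budget", {
  sim <- tiny_scan()
  av <- averaged(sim)
  reg <- find_beam_region(av$flat, av$dark)
  att <- normalize_attenuation(sim$stacks$tomo$frames[[1]], av$dark, av$flat)
  fit <- fit_projection(att, sim$truth$emap, reg, sim$truth$spectra)
  truth <- t(sim$truth$rho_t[1, , ])
  ok <- !is.na(fit$projected_density[1, ])
  expect_gt(sum(ok), 150)
  expect_lt(max(abs(fit$projected_density[, ok] - truth[, ok])),
            1e-9 * max(truth))
  expect_lt(max(fit$residual_rms, na.rm = TRUE), 1e-10)
  # a dead column yields NA without harming its neighbours
  att2 <- att
  att2$values[, 100] <- NA
  fit2 <- fit_projection(att2, sim$truth$emap, reg, sim$truth$spectra)
  expect_true(all(is.na(fit2$projected_density[, 100])))
  expect_equal(fit2$projected_density[, 99], fit$projected_density[, 99])
  # batch contract: 1024 columns x 200 pixels x 4 materials in < 2 s
  n_rows <- 200; n_cols <- 1024
  tr <- structure(list(row = rep(100, n_cols), fwhm = rep(3, n_cols),
                       valid = rep(TRUE, n_cols), smooth_window = 3L),
                  class = "edge_trace")
  em <- energy_map_one_point(tr, default_sim_geometry(), n_rows)
  A <- structure(list(values = matrix(0.5, n_rows, n_cols),
                      mask = matrix(TRUE, n_rows, n_cols)),
                 class = "attenuation_image")
  elapsed <- system.time(
    fit_projection(A, em, full_region(n_rows, n_cols), four_refs,
                   keep_fitted = FALSE))["elapsed"]
  expect_lt(elapsed, 2)
})

test_that("assembly stacks projections and validates material lists", {
  sim <- tiny_scan()
  av <- averaged(sim)
  reg <- find_beam_region(av$flat, av$dark)
  fits <- lapply(sim$stacks$tomo$frames, function(fr)
    fit_projection(normalize_attenuation(fr, av$dark, av$flat),
                   sim$truth$emap, reg, sim$truth$spectra,
                   keep_fitted = FALSE))
  m <- assemble(fits, "scan")
  expect_equal(dim(m$maps$selenate), c(3, 200))
  ct <- assemble(fits, "ct", angles = sim$truth$angles)
  sg <- get_sinogram(ct, "selenate")
  expect_s3_class(sg, "material_sinogram")
  expect_equal(nrow(sg$values), 3)
  expect_error(assemble(fits, "ct"), "one angle per projection")
  bad <- fits
  bad[[2]]$materials <- rev(bad[[2]]$materials)
  expect_error(assemble(bad, "scan"), "inconsistent material")
  expect_error(get_sinogram(m, "selenate"), "ct-mode")
  expect_error(get_sinogram(ct, "gold"), "unknown material")
})

test_that("projected density converts to molar concentration", {
  se <- material_spectrum("Se", c(12, 13), c(7, 48),
                         provenance = "tabulated", molar_mass = 78.97)
  expect_equal(to_concentration(7.897e-3, 1, se), 100, tolerance = 1e-10)
  expect_equal(to_concentration(0, 1, se), 0)
  expect_error(to_concentration(1e-3, 0, se), "positive")
  no_m <- material_spectrum("x", c(12, 13), c(1, 2),
                            provenance = "synthetic")
  expect_error(to_concentration(1e-3, 1, no_m), "no molar mass")
})
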
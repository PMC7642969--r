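# Shared fixtures, built in code. Expensive simulations are cached per test
# run so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# minimal single-insert phantom (water holder + one selenate disk) sized for
# a 200-column detector at the default 9 um pixel
tiny_phantom <- function(insert_material = "selenate",
                         insert_density = 0.0189) {
  mats <- lapply(c(insert_material, "water"), species_spectrum)
  names(mats) <- c(insert_material, "water")
  structure(list(
    kind = "tiny", pixel_spacing = 9e-4, materials = mats,
    disks = data.frame(
      material = c("water", insert_material),
      cx = c(0, 0.02), cy = c(0, 0), r = c(0.06, 0.02),
      density = c(1.0, insert_density), stringsAsFactors = FALSE),
    inserts = data.frame(
      name = insert_material, material = insert_material,
      cx = 0.02, cy = 0, r = 0.02, density = insert_density,
      concentration_mM = NA, stringsAsFactors = FALSE)),
    class = "phantom")
}

# small noiseless calibration-only simulation (no phantom)
calib_sim <- function() {
  cached("calib_sim", simulate_scan(NULL, n_angles = 1L, n_rows = 400L,
                                    n_cols = 64L, noise = FALSE, seed = 7))
}

# small noiseless scan of the tiny phantom
tiny_scan <- function() {
  cached("tiny_scan", simulate_scan(tiny_phantom(), n_angles = 3L,
                                    n_rows = 400L, n_cols = 200L,
                                    noise = FALSE, seed = 8))
}

averaged <- function(sim) {
  list(dark = average_stack(sim$stacks$dark),
       flat = average_stack(sim$stacks$flat))
}

# synthetic attenuation image of a blurred edge at given per-column centers
edge_attenuation_image <- function(centers, n_rows, sigma = 1.2, lo = 0.3,
                                   hi = 2.3) {
  v <- vapply(centers, function(c0)
    lo + (hi - lo) * stats::pnorm(0:(n_rows - 1), c0, sigma),
    numeric(n_rows))
  structure(list(values = v, mask = matrix(TRUE, n_rows, length(centers))),
            class = "attenuation_image")
}

full_region <- function(n_rows, n_cols) {
  structure(list(top = rep(0L, n_cols), bottom = rep(n_rows, n_cols),
                 excluded = rep(FALSE, n_cols)),
            class = "beam_region")
}

# analytic sinogram of a centered uniform disk (density 1, radius r px)
disk_sinogram <- function(width, r, angles, shift = 0, density = 1) {
  c0 <- (width - 1) / 2
  s <- (0:(width - 1)) - c0 - shift
  v <- t(vapply(angles, function(a) {
    d <- abs(s)
    ifelse(d < r, 2 * density * sqrt(pmax(r^2 - d^2, 0)), 0)
  }, numeric(width)))
  structure(list(values = v, angles = angles, material = "disk"),
            class = "material_sinogram")
}
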
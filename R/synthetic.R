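# Forward simulator of the energy-dispersive imaging system: dark/flat/edge
# reference images and CT projection stacks with full ground truth, so every
# analysis stage can be validated without beamline data.
#
# The species near-edge spectra are stylized (edge jump + Gaussian peaks at
# the literature peak energies), not computed from atomic physics; they are
# used identically on the forward and inverse paths, so what is under test is
# the pipeline, not XANES theory.

#' Stylized near-edge reference spectra of the selenium species
#'
#' Analytic mass-attenuation curves per gram of compound: a Gaussian-broadened
#' edge jump (error-function profile, scaled by a smooth post-edge power-law
#' decline) plus Gaussian white-line peaks. Selenate carries its two
#' absorption peaks at 12.667 and 12.681 keV; selenite and selenomethionine
#' single peaks at slightly shifted positions; `selenium_film` is the sharp
#' elemental edge at 12.658 keV used for energy calibration.
#'
#' Passing `sigma > 0` returns the spectrum as seen at that Gaussian energy
#' resolution (widths added in quadrature) -- the exact analytic counterpart
#' of [blur_spectrum()].
#'
#' @param name One of `"selenate"`, `"selenite"`, `"selenomethionine"`,
#'   `"selenium_film"`, `"water"`.
#' @param energies Energy grid, keV (default: 12.2--13.2 keV, 0.2 eV step).
#' @param sigma Gaussian resolution sigma to fold in, keV. Default 0.
#' @return A [material_spectrum()] with provenance `"synthetic"` (`"water"`
#'   comes from the element tables, provenance `"tabulated"`).
#' @export
species_spectrum <- function(name, energies = NULL, sigma = 0) {
  if (is.null(energies)) energies <- seq(12.2, 13.2, by = 2e-4)
  if (name == "water") return(water_spectrum(energies))
  par <- switch(name,
    selenium_film = list(edge = 12.658, w = 4e-4, base = 7.3, jump = 40.9,
                         M = 78.97, peaks = NULL),
    selenate = list(edge = 12.662, w = 8e-4, base = 3.6, jump = 17.1,
                    M = 188.94,
                    peaks = list(c(12.667, 14, 2.5e-3), c(12.681, 9, 3e-3))),
    selenite = list(edge = 12.660, w = 8e-4, base = 3.9, jump = 18.7,
                    M = 172.94,
                    peaks = list(c(12.664, 12, 2.5e-3))),
    selenomethionine = list(edge = 12.658, w = 8e-4, base = 3.5, jump = 16.5,
                            M = 196.11,
                            peaks = list(c(12.661, 8, 3e-3),
                                         c(12.672, 2, 5e-3))),
    stop("unknown species: ", name))
  w_eff <- sqrt(par$w^2 + sigma^2)
  mu <- par$base * (12.658 / energies)^2.9 +
    par$jump * stats::pnorm(energies, par$edge, w_eff) *
      (par$edge / energies)^2.75
  for (pk in par$peaks) {
    s_eff <- sqrt(pk[3]^2 + sigma^2)
    mu <- mu + pk[2] * (pk[3] / s_eff) *
      exp(-0.5 * ((energies - pk[1]) / s_eff)^2)
  }
  material_spectrum(name, energies, mu, provenance = "synthetic",
                    molar_mass = par$M)
}

#' Demonstration phantoms with recorded ground truth
#'
#' `three_species_disks`: a water-filled cylindrical holder (radius 3.5 mm)
#' containing three disk inserts (radius 0.8 mm) of selenate, selenite and
#' selenomethionine solutions, each prepared at 100 mM. `seedpod`: a central
#' insert (radius 1.2 mm) of selenomethionine at 7 mg/cm^3 in the water-filled
#' holder. Coordinates are in cm about the rotation axis.
#'
#' @param kind `"three_species_disks"` or `"seedpod"`.
#' @param pixel_spacing Phantom/reconstruction pixel spacing, cm. Default
#'   9e-4 (matches the default detector pixel).
#' @param n Grid side for the rasterized density maps. Default 1024.
#' @return A `phantom`: `materials` (list of [material_spectrum()]),
#'   `disks` (data frame material/cx/cy/r/density driving analytic
#'   projection), `inserts` (named truths: density g/cm^3 and, for
#'   solutions, concentration mM), `pixel_spacing`, and `grid` (n x n x
#'   n_materials density array).
#' @export
make_demo_phantom <- function(kind = c("three_species_disks", "seedpod"),
                              pixel_spacing = 9e-4, n = 1024L) {
  kind <- match.arg(kind)
  species <- c("selenate", "selenite", "selenomethionine")
  M <- c(selenate = 188.94, selenite = 172.94, selenomethionine = 196.11)
  holder_r <- 0.35
  if (kind == "three_species_disks") {
    conc_mM <- 100
    ang <- c(90, 210, 330) * pi / 180
    disks <- data.frame(
      material = c("water", species),
      cx = c(0, 0.18 * cos(ang)),
      cy = c(0, 0.18 * sin(ang)),
      r = c(holder_r, rep(0.08, 3)),
      density = c(1.0, conc_mM * M[species] / 1e6),  # mM * g/mol -> g/cm^3
      stringsAsFactors = FALSE)
    inserts <- data.frame(
      name = species, material = species,
      cx = disks$cx[-1], cy = disks$cy[-1], r = disks$r[-1],
      density = disks$density[-1],
      concentration_mM = rep(conc_mM, 3),
      stringsAsFactors = FALSE)
  } else {
    disks <- data.frame(
      material = c("water", "selenomethionine"),
      cx = c(0, 0), cy = c(0, 0), r = c(holder_r, 0.12),
      density = c(1.0, 7e-3),
      stringsAsFactors = FALSE)
    inserts <- data.frame(
      name = "seedpod", material = "selenomethionine",
      cx = 0, cy = 0, r = 0.12, density = 7e-3,
      concentration_mM = 7e-3 / M["selenomethionine"] * 1e6,
      stringsAsFactors = FALSE)
  }
  materials <- lapply(c(species, "water"), species_spectrum)
  names(materials) <- c(species, "water")
  # rasterized per-material density maps (reference/visualisation; the
  # analytic disk description drives the forward projection)
  ax <- (seq_len(n) - (n + 1) / 2) * pixel_spacing
  grid <- array(0, dim = c(n, n, length(materials)),
                dimnames = list(NULL, NULL, names(materials)))
  for (k in seq_len(nrow(disks))) {
    m <- disks$material[k]
    inside <- outer((ax - disks$cy[k])^2, (ax - disks$cx[k])^2, `+`) <=
      disks$r[k]^2
    grid[, , m] <- grid[, , m] + disks$density[k] * inside
  }
  structure(list(kind = kind, materials = materials, disks = disks,
                 inserts = inserts, pixel_spacing = pixel_spacing,
                 grid = grid),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("Phantom '%s': %d materials, %d insert(s), %.0f um pixels\n",
              x$kind, length(x$materials), nrow(x$inserts),
              x$pixel_spacing * 1e4))
  print(x$inserts[, c("name", "material", "density", "concentration_mM")])
  invisible(x)
}

#' Analytic line integrals through a disk phantom
#'
#' Projected density per material along parallel rays at one rotation angle:
#' each disk contributes an analytic chord `2 * sqrt(r^2 - d^2) * density`
#' where `d` is the ray-to-center distance. Exact (no raster error), the
#' ground truth for sinogram tests.
#'
#' @param phantom A [make_demo_phantom()] phantom (or any object with a
#'   `disks` data frame).
#' @param angle_deg Rotation angle, degrees.
#' @param n_cols Number of detector columns.
#' @param pixel_size_cm Detector column spacing at the sample, cm.
#' @param center Rotation-axis column (0-based, default `(n_cols - 1) / 2`).
#' @return Matrix `n_cols x n_materials` of projected densities, g/cm^2,
#'   with material names from `phantom$materials`.
#' @export
project_phantom <- function(phantom, angle_deg, n_cols,
                            pixel_size_cm = phantom$pixel_spacing,
                            center = (n_cols - 1) / 2) {
  mats <- names(phantom$materials)
  s <- ((0:(n_cols - 1)) - center) * pixel_size_cm
  phi <- angle_deg * pi / 180
  out <- matrix(0, n_cols, length(mats), dimnames = list(NULL, mats))
  for (k in seq_len(nrow(phantom$disks))) {
    dk <- phantom$disks[k, ]
    d <- abs(dk$cx * cos(phi) + dk$cy * sin(phi) - s)
    chord <- ifelse(d < dk$r, 2 * sqrt(pmax(dk$r^2 - d^2, 0)), 0)
    out[, dk$material] <- out[, dk$material] + dk$density * chord
  }
  out
}

#' Line integrals of a raster grid by rotation and summation
#'
#' Numerical counterpart of [project_phantom()]: bilinear rotation of the
#' density grid followed by summation along rows, times the pixel spacing.
#' Used to cross-check the analytic projection.
#'
#' @param grid Square density matrix, g/cm^3.
#' @param angle_deg Rotation angle, degrees.
#' @param pixel_spacing Grid spacing, cm.
#' @return Vector of projected densities (g/cm^2), one per grid column.
#' @export
project_grid <- function(grid, angle_deg, pixel_spacing) {
  n <- nrow(grid)
  stopifnot(ncol(grid) == n)
  c0 <- (n + 1) / 2
  phi <- angle_deg * pi / 180
  idx <- seq_len(n) - c0
  # sample the grid at points rotated by -phi so that summing over y
  # integrates along the ray direction for detector coordinate x
  xs <- outer(rep(1, n), idx)   # [y, x]
  ys <- outer(idx, rep(1, n))
  xr <- cos(phi) * xs - sin(phi) * ys + c0
  yr <- sin(phi) * xs + cos(phi) * ys + c0
  x0 <- floor(xr); y0 <- floor(yr)
  fx <- xr - x0; fy <- yr - y0
  val <- matrix(0, n, n)
  ok <- x0 >= 1 & x0 < n & y0 >= 1 & y0 < n
  g <- function(r, c) grid[cbind(r, c)]
  val[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * g(y0[ok], x0[ok]) +
    fx[ok] * (1 - fy[ok]) * g(y0[ok], x0[ok] + 1L) +
    (1 - fx[ok]) * fy[ok] * g(y0[ok] + 1L, x0[ok]) +
    fx[ok] * fy[ok] * g(y0[ok] + 1L, x0[ok] + 1L)
  colSums(val) * pixel_spacing
}

#' Default geometry of the simulated beamline
#'
#' Si(111) bent-Laue monochromator at the selenium K edge (12.658 keV),
#' 9 um detector pixels, 500 mm focus-to-detector distance.
#'
#' @return A [system_geometry()].
#' @export
default_sim_geometry <- function() {
  system_geometry(asymmetry_angle = 5, reflection = c(1, 1, 1),
                  edge_energy = 12.658, pixel_size = 0.009,
                  focus_to_detector = 500, energy_direction = 1L)
}

# ground-truth per-pixel energy map with a quadratic beam bow
truth_energy_map <- function(geometry, n_rows, n_cols, edge_row, bow) {
  cols <- 0:(n_cols - 1)
  edge_rows <- edge_row + bow * (cols - (n_cols - 1) / 2)^2
  trace <- structure(list(row = edge_rows, fwhm = rep(NA_real_, n_cols),
                          valid = rep(TRUE, n_cols), smooth_window = 1L),
                     class = "edge_trace")
  list(emap = energy_map_one_point(trace, geometry, n_rows),
       edge_rows = edge_rows)
}

# mu/rho cube [rows x cols x materials] for spectra on a per-column energy map
mu_cube <- function(spectra, emap) {
  nr <- nrow(emap$energies); nc <- ncol(emap$energies)
  cube <- array(NA_real_, c(nr, nc, length(spectra)),
                dimnames = list(NULL, NULL, names(spectra)))
  for (m in seq_along(spectra)) {
    sp <- spectra[[m]]
    cube[, , m] <- array(
      stats::approx(sp$energy_grid, sp$mu_rho, xout = as.vector(emap$energies),
                    rule = 1)$y, c(nr, nc))
  }
  cube
}

#' Simulate a full energy-dispersive imaging scan
#'
#' Forward model of the system: a near-Gaussian vertical flat-beam profile, a
#' per-column energy axis following the one-point Bragg map with a quadratic
#' beam bow, reference edge images (elemental film and two-peak speciation
#' solution), and CT projection images with
#' `counts = dark + (flat - dark) * flux * exp(-sum_m (mu/rho)_m(E) rho_t_m)`
#' where the `rho_t` are analytic line integrals through the phantom.
#' Reference spectra are pre-blurred by `sigma_E` before exponentiation.
#' Poisson counting noise (plus Gaussian detector read noise) is applied when
#' `noise = TRUE`; all randomness is deterministic given `seed`.
#'
#' @param phantom [make_demo_phantom()] phantom (or `NULL` for an empty
#'   sample, e.g. when only calibration images are needed).
#' @param geometry [system_geometry()]; default [default_sim_geometry()].
#' @param n_angles Number of CT projections over `[0, 180)` degrees.
#' @param n_rows,n_cols Detector format. Defaults 400 x 1024.
#' @param counts_flat Mean photon counts at the beam-profile peak. Default
#'   1e4.
#' @param noise Apply Poisson/read noise. Default `TRUE`.
#' @param decay_to Final flux fraction of a linear beam decay across the scan
#'   (1 = no decay). Default 1.
#' @param bow Quadratic edge-bow coefficient, px/column^2. Default 1e-4.
#' @param sigma_E Gaussian energy-resolution sigma, keV. Default 5.4e-4
#'   (relative edge width about 1e-4).
#' @param beam_center_row,beam_fwhm_rows Vertical beam profile parameters;
#'   defaults place the beam mid-detector with FWHM 30% of the rows (120
#'   rows on the default format).
#' @param n_dark,n_flat Frames per correction stack. Default 10.
#' @param seed Integer seed controlling all randomness.
#' @return List with `stacks` (named [image_stack()]s: `dark`, `flat`,
#'   `edge_elemental`, `edge_speciation`, `tomo`) and `truth`
#'   (`simulation_truth`: `emap`, `edge_rows`, `flux_factors`, `rho_t`
#'   (angles x columns x materials), `sigma_E`, `angles`, blurred `spectra`).
#' @export
simulate_scan <- function(phantom = NULL, geometry = default_sim_geometry(),
                          n_angles = 180L, n_rows = 400L, n_cols = 1024L,
                          counts_flat = 1e4, noise = TRUE, decay_to = 1,
                          bow = 1e-4, sigma_E = 5.4e-4,
                          beam_center_row = n_rows / 2,
                          beam_fwhm_rows = 0.3 * n_rows,
                          n_dark = 10L, n_flat = 10L, seed = 1L) {
  stopifnot(counts_flat > 0, decay_to > 0, decay_to <= 1)
  set.seed(seed)
  tm <- truth_energy_map(geometry, n_rows, n_cols, beam_center_row, bow)
  emap <- tm$emap
  # vertical beam profile (identical across columns)
  sig_b <- beam_fwhm_rows / (2 * sqrt(2 * log(2)))
  prof <- counts_flat * exp(-0.5 * ((0:(n_rows - 1)) - beam_center_row)^2 /
                              sig_b^2)
  flat_true <- matrix(prof, n_rows, n_cols)
  dark_level <- 100
  dark_frame <- function() matrix(dark_level + if (noise)
    stats::rnorm(n_rows * n_cols, sd = 2) else 0, n_rows, n_cols)
  count_frame <- function(lambda) {
    lam <- pmax(lambda, 0)
    cnt <- if (noise) matrix(stats::rpois(length(lam), lam), n_rows, n_cols)
           else lam
    cnt + dark_frame()
  }
  dark <- image_stack(replicate(n_dark, dark_frame(), simplify = FALSE),
                      role = "dark")
  flat <- image_stack(replicate(n_flat, count_frame(flat_true),
                                simplify = FALSE), role = "flat")
  # reference edge images
  film <- species_spectrum("selenium_film", sigma = sigma_E)
  specn <- species_spectrum("selenate", sigma = sigma_E)
  film_mu <- mu_cube(list(selenium_film = film), emap)[, , 1]
  spec_mu <- mu_cube(list(selenate = specn), emap)[, , 1]
  rho_film <- 4.79 * 0.02       # 0.2 mm elemental selenium film, g/cm^2
  rho_specn <- 0.08             # selenate solution path, g/cm^2 of compound
  edge_el <- image_stack(list(count_frame(flat_true *
                                            exp(-film_mu * rho_film))),
                         role = "edge")
  edge_sp <- image_stack(list(count_frame(flat_true *
                                            exp(-spec_mu * rho_specn))),
                         role = "edge")
  # tomo projections
  angles <- seq(0, 180, length.out = n_angles + 1L)[seq_len(n_angles)]
  flux <- seq(1, decay_to, length.out = n_angles)
  tomo_frames <- vector("list", n_angles)
  rho_t <- NULL
  spectra_blurred <- NULL
  if (!is.null(phantom)) {
    spectra_blurred <- lapply(names(phantom$materials), function(m)
      if (m == "water") phantom$materials[[m]]
      else species_spectrum(m, sigma = sigma_E))
    names(spectra_blurred) <- names(phantom$materials)
    cube <- mu_cube(spectra_blurred, emap)
    n_mat <- length(spectra_blurred)
    rho_t <- array(0, c(n_angles, n_cols, n_mat),
                   dimnames = list(NULL, NULL, names(spectra_blurred)))
    for (a in seq_len(n_angles)) {
      pt <- project_phantom(phantom, angles[a], n_cols,
                            pixel_size_cm = geometry$pixel_size / 10)
      rho_t[a, , ] <- pt[, names(spectra_blurred)]
      A <- matrix(0, n_rows, n_cols)
      for (m in seq_len(n_mat))
        A <- A + cube[, , m] * rep(pt[, m], each = n_rows)
      tomo_frames[[a]] <- count_frame(flat_true * flux[a] * exp(-A))
    }
  } else {
    for (a in seq_len(n_angles))
      tomo_frames[[a]] <- count_frame(flat_true * flux[a])
  }
  tomo <- image_stack(tomo_frames, role = "tomo", angles = angles)
  truth <- structure(list(emap = emap, edge_rows = tm$edge_rows,
                          flux_factors = flux, rho_t = rho_t,
                          sigma_E = sigma_E, angles = angles,
                          spectra = spectra_blurred,
                          geometry = geometry, phantom = phantom),
                     class = "simulation_truth")
  list(stacks = list(dark = dark, flat = flat, edge_elemental = edge_el,
                     edge_speciation = edge_sp, tomo = tomo),
       truth = truth)
}
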
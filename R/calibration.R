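# Energy calibration of the energy-dispersed detector field: flat/dark
# normalization, useful-beam-region detection, per-column absorption-edge
# localization, one-point and two-point energy maps, and the FWHM-of-derivative
# energy-resolution estimate.
#
# Row/pixel conventions: rows are indexed 0-based from the top of the image;
# beam-region intervals are half-open [top, bottom). Subpixel positions are
# continuous in the same coordinate.

#' Flat/dark normalization to attenuation
#'
#' Computes `-ln[(tomo - dark) / (flat - dark)]` per pixel, the measured line
#' integral `sum_i (mu/rho)_i (rho t)_i`. Pixels where either difference is
#' non-positive are masked (`NA` values, mask `FALSE`) rather than erroring.
#'
#' With `debias = TRUE` the first-order log-of-Poisson bias is removed:
#' for counts `N ~ Poisson(lambda)`, `E[-ln N] = -ln(lambda) + 1/(2 lambda) +
#' O(lambda^-2)`, so low-count pixels (strong absorption, beam-profile edges)
#' carry a systematic positive attenuation bias that the least-squares fit
#' would misread as material. The plug-in correction subtracts
#' `1/(2 (tomo - dark))` and adds `1/(2 n_flat_frames (flat - dark))`.
#'
#' @param tomo,dark,flat 2-D count matrices of one shape (dark and flat are
#'   the averaged correction images).
#' @param debias Apply the first-order Poisson log-bias correction. Default
#'   `FALSE` (the plain negative-log normalization).
#' @param n_flat_frames Number of frames averaged into `flat` (scales its
#'   bias term). Default 1.
#' @return An `attenuation_image`: list with `values` (matrix, `NA` where
#'   masked) and `mask` (logical matrix).
#' @export
normalize_attenuation <- function(tomo, dark, flat, debias = FALSE,
                                  n_flat_frames = 1L) {
  if (!all(dim(tomo) == dim(dark)) || !all(dim(tomo) == dim(flat)))
    stop("tomo, dark and flat must share one shape")
  num <- tomo - dark
  den <- flat - dark
  mask <- num > 0 & den > 0
  if (!any(mask))
    stop("all pixels masked: check image role assignment (dark/flat/tomo)")
  values <- matrix(NA_real_, nrow(tomo), ncol(tomo))
  values[mask] <- -log(num[mask] / den[mask])
  if (debias)
    values[mask] <- values[mask] - 1 / (2 * num[mask]) +
      1 / (2 * n_flat_frames * den[mask])
  structure(list(values = values, mask = mask), class = "attenuation_image")
}

#' Find the useful beam region from the flat image
#'
#' The vertical beam profile is near-Gaussian; per column, the largest
#' contiguous run of rows with `(flat - dark) >= threshold_fraction * column
#' maximum` is retained. Columns whose run is shorter than `min_height` rows
#' (or whose maximum is non-positive) are excluded.
#'
#' @param flat,dark Averaged flat and dark count matrices.
#' @param threshold_fraction Fraction of the per-column maximum, in (0, 1).
#'   Default 0.10.
#' @param min_height Minimum run height in rows. Default 8.
#' @return A `beam_region`: per-column integer `top` and `bottom` (0-based,
#'   half-open) and logical `excluded`.
#' @export
find_beam_region <- function(flat, dark, threshold_fraction = 0.10,
                             min_height = 8L) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    stop("threshold_fraction must lie in (0, 1)")
  prof <- flat - dark
  nc <- ncol(prof); nr <- nrow(prof)
  top <- integer(nc); bottom <- integer(nc); excluded <- logical(nc)
  for (j in seq_len(nc)) {
    col <- prof[, j]
    m <- max(col)
    if (!is.finite(m) || m <= 0) { excluded[j] <- TRUE; next }
    above <- col >= threshold_fraction * m
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    if (r$lengths[best] < min_height) { excluded[j] <- TRUE; next }
    top[j] <- starts[best] - 1L        # 0-based
    bottom[j] <- ends[best]            # half-open
  }
  if (all(excluded)) stop("beam absent: no column passes the threshold")
  structure(list(top = top, bottom = bottom, excluded = excluded),
            class = "beam_region")
}

#' @export
print.beam_region <- function(x, ...) {
  ok <- !x$excluded
  cat(sprintf("Beam region: %d/%d columns retained, median height %d rows\n",
              sum(ok), length(ok),
              as.integer(stats::median(x$bottom[ok] - x$top[ok]))))
  invisible(x)
}

# boxcar smoothing along a vector, replicated ends, odd window
boxcar <- function(y, window) {
  window <- as.integer(window)
  if (window <= 1L) return(y)
  if (window %% 2L == 0L) window <- window + 1L
  half <- window %/% 2L
  ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
  as.numeric(stats::filter(ypad, rep(1 / window, window),
                           sides = 2))[(half + 1):(half + length(y))]
}

# parabolic refinement of a discrete peak at index i (1-based) of curve d;
# returns subpixel offset in (-0.5, 0.5)
parabolic_offset <- function(d, i) {
  if (i <= 1L || i >= length(d)) return(0)
  denom <- d[i - 1] - 2 * d[i] + d[i + 1]
  if (denom >= 0) return(0)
  off <- 0.5 * (d[i - 1] - d[i + 1]) / denom
  max(min(off, 0.5), -0.5)
}

# FWHM (in samples) of a discrete peak at index i by linear interpolation of
# the half-maximum crossings; NA when a crossing is not bracketed
peak_fwhm <- function(d, i) {
  if (i <= 1L || i >= length(d) || !is.finite(d[i])) return(NA_real_)
  half <- d[i] / 2
  lo <- NA_real_; hi <- NA_real_
  k <- i
  while (k > 1L) {
    if (!is.finite(d[k - 1])) break
    if (d[k - 1] <= half && d[k] > half) {
      lo <- (k - 1) + (half - d[k - 1]) / (d[k] - d[k - 1]); break
    }
    k <- k - 1L
  }
  k <- i
  while (k < length(d)) {
    if (!is.finite(d[k + 1])) break
    if (d[k + 1] <= half && d[k] > half) {
      hi <- k + (d[k] - half) / (d[k] - d[k + 1]); break
    }
    k <- k + 1L
  }
  hi - lo
}

# fill NA pixels inside a column segment by linear interpolation
fill_na <- function(y) {
  if (!anyNA(y)) return(y)
  ok <- which(!is.na(y))
  if (length(ok) < 2L) return(y)
  stats::approx(ok, y[ok], xout = seq_along(y), rule = 2)$y
}

#' Locate the absorption edge in every detector column
#'
#' Takes the first difference along rows of the boxcar-smoothed attenuation of
#' the edge image, finds the peak of its magnitude inside the beam region,
#' refines the location to subpixel precision by parabolic interpolation
#' through the three points around the maximum, and measures the peak's FWHM.
#' Columns whose peak prominence is below `5 * MAD` of the derivative (or
#' absent entirely) are flagged invalid. Across columns the trace follows the
#' beam's bow caused by non-uniform crystal bending.
#'
#' @param edge_attenuation `attenuation_image` of the elemental-reference edge
#'   image (from [normalize_attenuation()]).
#' @param region [find_beam_region()] result.
#' @param smooth_window Boxcar window in pixels (default 3).
#' @return An `edge_trace`: per-column subpixel `row` (0-based), derivative
#'   `fwhm` in pixels, and logical `valid`.
#' @export
find_edge <- function(edge_attenuation, region, smooth_window = 3L) {
  v <- edge_attenuation$values
  nc <- ncol(v)
  row <- rep(NA_real_, nc); fwhm <- rep(NA_real_, nc); valid <- logical(nc)
  for (j in seq_len(nc)) {
    if (region$excluded[j]) next
    rows <- (region$top[j] + 1L):region$bottom[j]   # 1-based R indices
    if (length(rows) < 5L) next
    y <- fill_na(v[rows, j])
    if (anyNA(y)) next
    d <- abs(diff(boxcar(y, smooth_window)))
    i <- which.max(d)
    prom <- d[i] - stats::median(d)
    floor_ <- max(5 * stats::mad(d), 1e-8)
    if (!is.finite(prom) || d[i] < floor_ || prom <= 0) next
    off <- parabolic_offset(d, i)
    # derivative sample i sits between rows[i] and rows[i+1]
    row[j] <- (rows[i] - 1) + 0.5 + off
    fwhm[j] <- peak_fwhm(d, i)
    valid[j] <- TRUE
  }
  if (!any(valid)) stop("no valid column: absorption edge not found")
  structure(list(row = row, fwhm = fwhm, valid = valid,
                 smooth_window = as.integer(smooth_window)),
            class = "edge_trace")
}

#' @export
print.edge_trace <- function(x, ...) {
  ok <- x$valid
  cat(sprintf(
    "Edge trace: %d/%d valid columns, row %.2f-%.2f, median FWHM %.2f px\n",
    sum(ok), length(ok), min(x$row[ok]), max(x$row[ok]),
    stats::median(x$fwhm[ok], na.rm = TRUE)))
  invisible(x)
}

#' Locate multiple absorption peaks per column
#'
#' Finds the `n_peaks` most prominent local maxima of the boxcar-smoothed
#' attenuation along each column of a speciation reference image (e.g. the
#' two near-edge peaks of selenate), refined to subpixel precision. Used to
#' build the anchors for two-point energy calibration.
#'
#' @param attenuation `attenuation_image` of the speciation reference.
#' @param region [find_beam_region()] result.
#' @param n_peaks Number of peaks to return per column.
#' @param smooth_window Boxcar window in pixels (default 3).
#' @return List with `rows` (`n_peaks` x `n_columns` matrix of subpixel rows,
#'   0-based, sorted by row within each column) and logical `valid` per
#'   column.
#' @export
find_absorption_peaks <- function(attenuation, region, n_peaks = 2L,
                                  smooth_window = 3L) {
  v <- attenuation$values
  nc <- ncol(v)
  rows_out <- matrix(NA_real_, n_peaks, nc)
  valid <- logical(nc)
  for (j in seq_len(nc)) {
    if (region$excluded[j]) next
    rows <- (region$top[j] + 1L):region$bottom[j]
    if (length(rows) < 2L * n_peaks + 3L) next
    y <- fill_na(v[rows, j])
    if (anyNA(y)) next
    ys <- boxcar(y, smooth_window)
    n <- length(ys)
    loc <- which(ys[2:(n - 1)] > ys[1:(n - 2)] &
                 ys[2:(n - 1)] >= ys[3:n]) + 1L
    if (length(loc) < n_peaks) next
    prom <- ys[loc] - stats::median(ys)
    keep <- loc[order(prom, decreasing = TRUE)][seq_len(n_peaks)]
    keep <- sort(keep)
    sub <- vapply(keep, function(i) (rows[i] - 1) + parabolic_offset(ys, i),
                  0)
    rows_out[, j] <- sub
    valid[j] <- TRUE
  }
  if (!any(valid)) stop("no valid column: absorption peaks not found")
  list(rows = rows_out, valid = valid)
}

#' Calibration anchors for the two-point energy map
#'
#' Each anchor pairs a (per-column, subpixel) detector row with a known photon
#' energy; the Bragg angles are derived from the geometry. Anchor 1 is the
#' first (lower-energy) spectral feature.
#'
#' @param p1,p2 Subpixel detector rows (scalars or one per column), 0-based.
#' @param E1,E2 Known energies of the two features, keV; `E1 != E2`.
#' @param geometry [system_geometry()].
#' @return An object of class `calibration_anchors`.
#' @export
calibration_anchors <- function(p1, E1, p2, E2, geometry) {
  if (any(p1 == p2, na.rm = TRUE) || E1 == E2)
    stop("degenerate anchors: the two reference features must differ in both",
         " pixel position and energy")
  structure(list(p1 = p1, E1 = E1, theta1 = bragg_angle(E1, geometry),
                 p2 = p2, E2 = E2, theta2 = bragg_angle(E2, geometry)),
            class = "calibration_anchors")
}

#' Anchors from detected speciation peaks
#'
#' Pairs the per-column peak rows from [find_absorption_peaks()] with their
#' known energies, respecting the geometry's energy direction (for
#' `energy_direction = +1` the lower row carries the higher energy).
#'
#' @param peaks Result of [find_absorption_peaks()] with two peaks.
#' @param energies Length-2 vector of the two feature energies, keV (any
#'   order).
#' @param geometry [system_geometry()].
#' @return A [calibration_anchors()] object with per-column rows.
#' @export
anchors_from_peaks <- function(peaks, energies, geometry) {
  stopifnot(nrow(peaks$rows) == 2L, length(energies) == 2L)
  E <- sort(energies)                      # E[1] low, E[2] high
  r_lo <- peaks$rows[1, ]; r_hi <- peaks$rows[2, ]   # by row order
  if (geometry$energy_direction > 0) {
    # energy decreases with row: smaller row <-> higher energy
    calibration_anchors(p1 = r_hi, E1 = E[1], p2 = r_lo, E2 = E[2],
                        geometry = geometry)
  } else {
    calibration_anchors(p1 = r_lo, E1 = E[1], p2 = r_hi, E2 = E[2],
                        geometry = geometry)
  }
}

new_energy_map <- function(energies, method) {
  structure(list(energies = energies, method = method), class = "energy_map")
}

#' @export
print.energy_map <- function(x, ...) {
  rng <- range(x$energies, na.rm = TRUE)
  cat(sprintf("Energy map (%s): %d x %d px, %.4f-%.4f keV\n",
              if (is.null(x$method)) "?" else x$method,
              nrow(x$energies), ncol(x$energies), rng[1], rng[2]))
  invisible(x)
}

#' One-point per-pixel energy map
#'
#' For every column, the ray hitting pixel `p` leaves the focus at an angular
#' offset `alpha = arctan[(p - p_K) * pixel_size / focus_to_detector]` from
#' the K-edge ray; its Bragg angle is `theta_K + energy_direction * alpha` and
#' its energy follows Bragg's law. The map reproduces the edge energy exactly
#' at the traced edge row of each column, honouring the beam bow.
#'
#' @param trace [find_edge()] result (per-column edge rows).
#' @param geometry [system_geometry()].
#' @param n_rows Number of detector rows.
#' @return An `energy_map` (matrix `n_rows` x `n_columns`, keV; `NA` for
#'   invalid columns).
#' @export
energy_map_one_point <- function(trace, geometry, n_rows) {
  theta_K <- bragg_angle(geometry$edge_energy, geometry)
  nc <- length(trace$row)
  p <- 0:(n_rows - 1)
  E <- matrix(NA_real_, n_rows, nc)
  for (j in seq_len(nc)) {
    if (!trace$valid[j]) next
    alpha <- atan((p - trace$row[j]) * geometry$pixel_size /
                    geometry$focus_to_detector)
    theta <- theta_K + geometry$energy_direction * alpha
    if (any(theta <= 0 | theta >= pi / 2))
      stop("Bragg angle outside (0, pi/2); check geometry")
    E[, j] <- bragg_energy(theta, geometry)
  }
  new_energy_map(E, "one_point")
}

#' Two-point per-pixel energy map
#'
#' Anchored at two spectral features of known energy, which removes the
#' dependence on the assumed focus-to-detector distance: an effective focus
#' distance `F_eff = pixel_size * (p1 - p2) / tan(theta1 - theta2)` is derived
#' per column, then `theta(p) = theta1 + arctan[(p - p1) * pixel_size /
#' F_eff]`. The map reproduces both anchor energies exactly.
#'
#' @param anchors [calibration_anchors()] (scalar or per-column rows).
#' @param geometry [system_geometry()].
#' @param n_rows Number of detector rows.
#' @param n_cols Number of detector columns (defaults to the anchor vector
#'   length when per-column).
#' @return An `energy_map` (keV; `NA` for columns without anchors).
#' @export
energy_map_two_point <- function(anchors, geometry, n_rows, n_cols = NULL) {
  p1 <- anchors$p1; p2 <- anchors$p2
  if (is.null(n_cols)) n_cols <- max(length(p1), length(p2))
  p1 <- rep_len(p1, n_cols); p2 <- rep_len(p2, n_cols)
  dth <- anchors$theta1 - anchors$theta2
  if (dth == 0) stop("degenerate anchors: equal Bragg angles")
  p <- 0:(n_rows - 1)
  E <- matrix(NA_real_, n_rows, n_cols)
  for (j in seq_len(n_cols)) {
    if (is.na(p1[j]) || is.na(p2[j])) next
    F_eff <- geometry$pixel_size * (p1[j] - p2[j]) / tan(dth)
    theta <- anchors$theta1 +
      atan((p - p1[j]) * geometry$pixel_size / F_eff)
    if (any(theta <= 0 | theta >= pi / 2))
      stop("Bragg angle outside (0, pi/2); check anchors")
    E[, j] <- bragg_energy(theta, geometry)
  }
  new_energy_map(E, "two_point")
}

#' Energy at a subpixel row of one column
#'
#' Linear interpolation of the energy map along a column; used e.g. to read
#' the calibrated energy at a detected edge row.
#'
#' @param emap An `energy_map`.
#' @param row Subpixel row (0-based), vectorized.
#' @param col Column index (1-based), vectorized with `row`.
#' @return Energies, keV.
#' @export
energy_at <- function(emap, row, col) {
  n_rows <- nrow(emap$energies)
  mapply(function(r, j) {
    stats::approx(0:(n_rows - 1), emap$energies[, j], xout = r)$y
  }, row, col)
}

# Predicted half-max-crossing FWHM of |diff(boxcar_w(blurred step))| for a
# Gaussian edge of width sigma_px, averaged over subpixel sampling phases.
# The estimator's own kernel (first difference + boxcar) dominates below
# about half a pixel, where this response saturates near w.
kernel_response_fwhm <- function(sigma_px, w,
                                 phases = seq(0, 0.9, by = 0.1)) {
  mean(vapply(phases, function(ph) {
    half_span <- max(10, ceiling(8 * sigma_px + 2 * w))
    x <- seq(-half_span, half_span) + ph
    d <- abs(diff(boxcar(stats::pnorm(x, 0, sigma_px), w)))
    peak_fwhm(d, which.max(d))
  }, 0))
}

#' Estimate the system energy resolution from the edge width
#'
#' The per-column FWHM of the derivative of the edge absorption profile
#' measures the combined core-hole and monochromator resolution. The median
#' FWHM across valid columns (robust to bow-induced outliers) is deconvolved
#' from the estimator's own sampling kernel (first difference plus boxcar
#' smoothing) by numerically inverting the kernel's exact response to a
#' Gaussian edge; below about half a pixel the response saturates and the
#' estimate is floored there (the discretization floor). The result is
#' converted to energy through the local energy-per-pixel gradient at the
#' edge row.
#'
#' @param trace [find_edge()] result.
#' @param emap Energy map covering the same columns.
#' @param geometry [system_geometry()].
#' @return A `resolution_estimate`: `fwhm_energy` (keV), `gaussian_sigma`
#'   (keV), `relative` (dimensionless `FWHM / E_edge`), `fwhm_pixels`, and
#'   `at_floor` (logical: the width was below the measurable floor).
#' @export
estimate_resolution <- function(trace, emap, geometry) {
  ok <- trace$valid & !is.na(trace$fwhm)
  if (!any(ok)) stop("invalid trace: no measurable edge width")
  w <- if (is.null(trace$smooth_window)) 3L else trace$smooth_window
  fwhm_px <- stats::median(trace$fwhm[ok])
  sigma_floor <- 0.5
  at_floor <- fwhm_px <= kernel_response_fwhm(sigma_floor, w)
  sigma_px <- if (at_floor) sigma_floor else
    stats::uniroot(function(s) kernel_response_fwhm(s, w) - fwhm_px,
                   c(sigma_floor, max(4 * fwhm_px, 2)), tol = 1e-4)$root
  fwhm_corr <- 2 * sqrt(2 * log(2)) * sigma_px
  cols <- which(ok)
  dEdp <- vapply(cols, function(j) {
    r <- max(min(round(trace$row[j]), nrow(emap$energies) - 2), 1)
    abs(emap$energies[r + 2, j] - emap$energies[r, j]) / 2
  }, 0)
  fwhm_E <- fwhm_corr * stats::median(dEdp)
  structure(list(fwhm_energy = fwhm_E,
                 gaussian_sigma = fwhm_E / (2 * sqrt(2 * log(2))),
                 relative = fwhm_E / geometry$edge_energy,
                 fwhm_pixels = fwhm_corr, at_floor = at_floor),
            class = "resolution_estimate")
}

#' @export
print.resolution_estimate <- function(x, ...) {
  cat(sprintf(
    "Energy resolution: FWHM %.3g keV (%.2f px), sigma %.3g keV, dE/E %.3g\n",
    x$fwhm_energy, x$fwhm_pixels, x$gaussian_sigma, x$relative))
  invisible(x)
}
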
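# CT utilities: beam-decay correction via empty margins, automatic rotation
# center finding, and filtered back projection reconstruction.

#' Correct storage-ring beam decay using empty margins
#'
#' The incident flux decays across a CT scan; a multiplicative count factor
#' becomes an additive constant in attenuation. With sample-free columns on
#' both sides of the field of view, each projection's offset is estimated as
#' the mean attenuation over the margin pixels and subtracted from the whole
#' projection.
#'
#' @param attenuations List of `attenuation_image`s (or plain matrices) in
#'   acquisition order.
#' @param margins Integer vector `c(left, right)`: margin widths in columns;
#'   both must be positive and the margins must be sample-free (caller's
#'   responsibility).
#' @param region Optional `beam_region`: restricts the margin average to the
#'   useful beam rows, excluding the noisy out-of-beam pixels.
#' @return List: `corrected` (same type as input) and `offsets` (numeric,
#'   one per projection; equals `-log(flux factor)` for pure decay).
#' @export
decay_correct <- function(attenuations, margins, region = NULL) {
  margins <- as.integer(margins)
  if (length(margins) == 1L) margins <- c(margins, margins)
  if (any(margins <= 0)) stop("zero-width margins: decay correction needs",
                              " empty columns on both sides")
  get_vals <- function(a) if (inherits(a, "attenuation_image")) a$values else a
  nc <- ncol(get_vals(attenuations[[1]]))
  if (sum(margins) >= nc) stop("margins wider than the image")
  mcols <- c(seq_len(margins[1]), (nc - margins[2] + 1L):nc)
  msel <- if (!is.null(region)) {
    sel <- matrix(FALSE, nrow(get_vals(attenuations[[1]])), nc)
    for (j in mcols)
      if (!region$excluded[j])
        sel[(region$top[j] + 1L):region$bottom[j], j] <- TRUE
    sel
  }
  offsets <- numeric(length(attenuations))
  corrected <- attenuations
  for (k in seq_along(attenuations)) {
    v <- get_vals(attenuations[[k]])
    offsets[k] <- if (is.null(msel)) mean(v[, mcols], na.rm = TRUE)
                  else mean(v[msel], na.rm = TRUE)
    if (inherits(attenuations[[k]], "attenuation_image"))
      corrected[[k]]$values <- v - offsets[k]
    else corrected[[k]] <- v - offsets[k]
  }
  list(corrected = corrected, offsets = offsets)
}

#' Find the rotation center of a sinogram
#'
#' Correlates the first projection with the horizontally flipped projection of
#' the nearest pair 180 degrees apart, over integer lags, and refines the best
#' lag by parabolic interpolation of the correlation peak. Falls back to
#' full-sinogram variance minimization only if requested.
#'
#' @param sinogram A `material_sinogram` (or matrix with an `angles`
#'   attribute/argument).
#' @param angles Projection angles in degrees (taken from the sinogram when
#'   absent).
#' @return Subpixel rotation-center column (0-based).
#' @export
find_center <- function(sinogram, angles = NULL) {
  v <- if (inherits(sinogram, "material_sinogram")) sinogram$values
       else as.matrix(sinogram)
  if (is.null(angles))
    angles <- if (inherits(sinogram, "material_sinogram")) sinogram$angles
              else attr(sinogram, "angles")
  if (is.null(angles) || nrow(v) < 2L)
    stop("rotation-center search needs >= 2 projections with angles")
  step <- stats::median(diff(sort(angles)))
  span <- max(angles) - min(angles)
  if (span + 1.5 * step < 180)
    stop("angular span < 180 degrees: cannot pair opposed projections")
  # nearest pair 180 degrees apart
  dif <- abs(outer(angles, angles, `-`)) - 180
  best <- which(abs(dif) == min(abs(dif)), arr.ind = TRUE)[1, ]
  p0 <- v[best[2], ]; p180 <- v[best[1], ]
  p0[is.na(p0)] <- 0; p180[is.na(p180)] <- 0
  q <- rev(p180)
  n <- length(p0)
  # p180 flipped about center c equals q shifted by delta = (n-1) - 2c
  lags <- -(n %/% 2):(n %/% 2)
  score <- vapply(lags, function(d) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1 & j <= n
    if (sum(ok) < n %/% 4) return(-Inf)
    a <- p0[i[ok]]; b <- q[j[ok]]
    sa <- a - mean(a); sb <- b - mean(b)
    den <- sqrt(sum(sa^2) * sum(sb^2))
    if (den == 0) 0 else sum(sa * sb) / den
  }, 0)
  k <- which.max(score)
  off <- if (k > 1 && k < length(lags) && all(is.finite(score[(k-1):(k+1)])))
    parabolic_offset(-score, k) else 0
  delta <- lags[k] + off
  (n - 1 - delta) / 2
}

# Kak & Slaney discrete ramp kernel (band-limited |f|), length n (even)
ramp_kernel <- function(n) {
  h <- numeric(n)
  h[1] <- 0.25
  k <- seq(1, n / 2, by = 2)
  h[1 + k] <- -1 / (pi * k)^2
  h[n + 1 - k] <- -1 / (pi * k)^2
  h
}

fbp_filter <- function(n, filter_name) {
  f <- 2 * Re(stats::fft(ramp_kernel(n)))
  if (filter_name == "ramp") return(f)
  freq <- c(0:(n / 2 - 1), -(n / 2):-1) / n   # fft frequencies
  if (filter_name == "shepp-logan") {
    w <- pi * freq[-1]
    f[-1] <- f[-1] * sin(w) / w
  } else if (filter_name == "cosine") {
    w <- seq(0, pi, length.out = n + 1)[seq_len(n)]
    f <- f * sin(w)[c((n / 2 + 1):n, 1:(n / 2))]
  } else if (filter_name == "hamming") {
    w <- 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    f <- f * w[c((n / 2 + 1):n, 1:(n / 2))]
  } else if (filter_name == "hann") {
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
    f <- f * w[c((n / 2 + 1):n, 1:(n / 2))]
  } else {
    stop("unknown filter name '", filter_name,
         "'; valid: ramp, shepp-logan, cosine, hamming, hann")
  }
  f
}

#' Filtered back projection reconstruction
#'
#' Standard parallel-beam FBP: each sinogram row is convolved with the
#' band-limited ramp kernel (optionally windowed) in the frequency domain
#' (zero-padded), then back-projected with linear interpolation. Sinogram
#' entries are line integrals in g/cm^2; the output is scaled by
#' `1 / pixel_spacing` so voxel values are volumetric densities in g/cm^3.
#' Pixels outside the inscribed circle are set to 0.
#'
#' @param sinogram A `material_sinogram`, or an angles-by-columns matrix.
#' @param center Subpixel rotation-center column (0-based); default
#'   `(n_cols - 1) / 2`. Use [find_center()] for automatic detection.
#' @param filter_name One of `"ramp"`, `"shepp-logan"`, `"cosine"`,
#'   `"hamming"`, `"hann"`.
#' @param pixel_spacing Detector column spacing, cm. Default 1 (pixel
#'   units).
#' @param angles Projection angles in degrees (taken from the sinogram when
#'   absent).
#' @return A `recon_map`: square `values` matrix (side = number of columns,
#'   g/cm^3), `pixel_spacing`, `filter_name`, `center_used`.
#' @export
reconstruct_fbp <- function(sinogram, center = NULL, filter_name = "ramp",
                            pixel_spacing = 1, angles = NULL) {
  v <- if (inherits(sinogram, "material_sinogram")) sinogram$values
       else as.matrix(sinogram)
  if (is.null(angles))
    angles <- if (inherits(sinogram, "material_sinogram")) sinogram$angles
              else attr(sinogram, "angles")
  if (is.null(angles)) stop("projection angles required")
  n <- ncol(v)
  if (is.null(center)) center <- (n - 1) / 2
  v[is.na(v)] <- 0
  npad <- 2^ceiling(log2(2 * n))
  filt <- fbp_filter(npad, filter_name)
  # filter all projections at once
  P <- rbind(t(v), matrix(0, npad - n, nrow(v)))
  Pf <- Re(stats::mvfft(stats::mvfft(P) * filt, inverse = TRUE)) / npad
  Pf <- Pf[seq_len(n), , drop = FALSE]     # [s, angle]
  # back projection on a square grid with the rotation axis at (center,center)
  idx <- 0:(n - 1)
  x <- outer(rep(1, n), idx - center)      # [row=y, col=x]
  y <- outer(idx - center, rep(1, n))
  inside <- x^2 + y^2 <= (n / 2)^2
  xi <- x[inside]; yi <- y[inside]
  acc <- numeric(length(xi))
  th <- angles * pi / 180
  for (a in seq_along(th)) {
    t <- xi * cos(th[a]) + yi * sin(th[a]) + center
    i0 <- floor(t)
    w <- t - i0
    ok <- i0 >= 0 & i0 < n - 1
    pa <- Pf[, a]
    acc[ok] <- acc[ok] + (1 - w[ok]) * pa[i0[ok] + 1L] + w[ok] * pa[i0[ok] + 2L]
  }
  out <- matrix(0, n, n)
  out[inside] <- acc * pi / (2 * length(th))
  structure(list(values = out / pixel_spacing, pixel_spacing = pixel_spacing,
                 filter_name = filter_name, center_used = center,
                 material = if (inherits(sinogram, "material_sinogram"))
                   sinogram$material),
            class = "recon_map")
}

#' @export
print.recon_map <- function(x, ...) {
  cat(sprintf(
    "Reconstruction%s: %d x %d px (%.4g cm/px), filter %s, center %.2f\n",
    if (!is.null(x$material)) paste0(" of ", x$material) else "",
    nrow(x$values), ncol(x$values), x$pixel_spacing, x$filter_name,
    x$center_used))
  cat(sprintf("  density range %.4g to %.4g g/cm^3\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
plot.recon_map <- function(x, ...) {
  graphics::image(x$values[nrow(x$values):1, ], asp = 1, useRaster = TRUE,
                  col = grDevices::gray.colors(256), axes = FALSE,
                  main = if (!is.null(x$material)) x$material else "", ...)
  invisible(x)
}

#' Mean reconstructed value inside a circular region
#'
#' Averages a reconstruction over the interior of a disk (shrunk by
#' `erode` to avoid partial-volume edge pixels) -- the standard readout for
#' phantom insert recovery.
#'
#' @param recon A `recon_map`.
#' @param cx,cy Disk center in cm relative to the rotation axis (x right,
#'   y down the sinogram-column axis).
#' @param r Disk radius, cm.
#' @param erode Fraction of the radius retained. Default 0.7.
#' @return Mean value over the region, g/cm^3.
#' @export
region_mean <- function(recon, cx, cy, r, erode = 0.7) {
  n <- nrow(recon$values)
  c0 <- recon$center_used
  ax <- ((0:(n - 1)) - c0) * recon$pixel_spacing
  inside <- outer((ax - cy)^2, (ax - cx)^2, `+`) <= (r * erode)^2
  mean(recon$values[inside])
}
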
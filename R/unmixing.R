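# Per-column least-squares decomposition of measured attenuation spectra into
# projected densities (rho*t, g/cm^2) of candidate materials, and assembly of
# per-projection results into 2-D maps or sinograms.

# Lawson-Hanson active-set non-negative least squares (small dense problems)
nnls_fit <- function(X, y, tol = 1e-10) {
  n <- ncol(X)
  passive <- logical(n)
  x <- numeric(n)
  w <- crossprod(X, y - X %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < 30L * n) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(X[, passive, drop = FALSE]), y)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(X, y - X %*% x)
  }
  x
}

build_design <- function(energies, references) {
  X <- vapply(references, resample_to_column, numeric(length(energies)),
              column_energies = energies)
  if (!is.matrix(X)) X <- matrix(X, nrow = length(energies))
  colnames(X) <- vapply(references, `[[`, "", "name")
  X
}

check_design <- function(X, cond_warn = 1e8) {
  Xc <- X[stats::complete.cases(X), , drop = FALSE]
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    # name the most collinear pair
    cn <- colnames(Xc)
    worst <- c(NA, NA); best <- -1
    for (a in seq_len(ncol(Xc) - 1)) for (b in (a + 1):ncol(Xc)) {
      ca <- abs(sum(Xc[, a] * Xc[, b])) /
        sqrt(sum(Xc[, a]^2) * sum(Xc[, b]^2))
      if (ca > best) { best <- ca; worst <- c(a, b) }
    }
    stop("degenerate reference pair: '", cn[worst[1]], "' and '",
         cn[worst[2]], "' are not linearly independent over the energy band")
  }
  k <- kappa(Xc, exact = FALSE)
  if (k > cond_warn)
    warning(sprintf(
      "ill-conditioned reference set (condition number %.2g): references %s",
      k, "should be distinctively different as a function of energy"))
  invisible(qrX$rank)
}

#' Least-squares material decomposition of one column spectrum
#'
#' Minimizes `sum_p (sum_m (mu/rho)_m(E_p) x_m - A_p)^2` over the projected
#' densities `x` (g/cm^2). Masked pixels (`NA` attenuation or reference
#' out-of-range) are dropped from the system, not imputed. Unconstrained by
#' default so that absent constituents diagnose themselves by near-zero
#' coefficients; optional non-negative mode for noisy low-concentration work.
#'
#' @param attenuation Per-pixel attenuation values (`NA` = masked).
#' @param energies Per-pixel energies, keV.
#' @param references List of [material_spectrum()] objects.
#' @param nonneg Constrain coefficients to be non-negative. Default `FALSE`.
#' @return List: `coefficients` (named, g/cm^2), `residual_rms`, `fitted`
#'   (full-length, `NA` at masked pixels), `dof`, `n_used`.
#' @export
fit_column <- function(attenuation, energies, references, nonneg = FALSE) {
  stopifnot(length(attenuation) == length(energies))
  X <- build_design(energies, references)
  use <- !is.na(attenuation) & stats::complete.cases(X)
  n_mat <- length(references)
  if (sum(use) <= n_mat)
    stop("insufficient pixels: ", sum(use), " unmasked for ", n_mat,
         " materials")
  check_design(X[use, , drop = FALSE])
  Xu <- X[use, , drop = FALSE]; yu <- attenuation[use]
  coef <- if (nonneg) nnls_fit(Xu, yu)
          else qr.coef(qr(Xu), yu)
  names(coef) <- colnames(X)
  fitted <- rep(NA_real_, length(attenuation))
  fitted[use] <- as.numeric(Xu %*% coef)
  res <- yu - fitted[use]
  list(coefficients = coef,
       residual_rms = sqrt(mean(res^2)),
       fitted = fitted,
       dof = sum(use) - n_mat,
       n_used = sum(use))
}

#' Fit every retained column of a projection
#'
#' Applies the per-column decomposition across the image: per column, the
#' pixels inside the beam region define the measured spectrum on that
#' column's energy axis. Columns excluded by the beam region, without a valid
#' energy axis, or failing the fit yield `NA` and do not abort the
#' projection.
#'
#' @param attenuation `attenuation_image` of the projection.
#' @param emap `energy_map` for the detector.
#' @param region `beam_region`.
#' @param references List of [material_spectrum()] objects.
#' @param nonneg Non-negativity constraint, default `FALSE`.
#' @param keep_fitted Keep the per-column fitted spectra (diagnostics);
#'   default `TRUE`.
#' @return A `fit_result`: `projected_density` (materials x columns matrix,
#'   g/cm^2), `residual_rms`, `dof`, `materials`, optional `fitted` and
#'   `energies` matrices.
#' @export
fit_projection <- function(attenuation, emap, region, references,
                           nonneg = FALSE, keep_fitted = TRUE) {
  v <- attenuation$values
  nc <- ncol(v); nr <- nrow(v)
  stopifnot(ncol(emap$energies) == nc, nrow(emap$energies) == nr)
  n_mat <- length(references)
  mats <- vapply(references, `[[`, "", "name")
  dens <- matrix(NA_real_, n_mat, nc, dimnames = list(mats, NULL))
  rms <- rep(NA_real_, nc); dof <- rep(NA_integer_, nc)
  fitted <- if (keep_fitted) matrix(NA_real_, nr, nc)
  # validate the reference set once on a representative column
  rep_col <- which(!region$excluded & !is.na(emap$energies[1, ]) |
                   !region$excluded & colSums(!is.na(emap$energies)) > 0)
  if (length(rep_col)) {
    j0 <- rep_col[ceiling(length(rep_col) / 2)]
    rows0 <- (region$top[j0] + 1L):region$bottom[j0]
    check_design(build_design(emap$energies[rows0, j0], references))
  }
  for (j in seq_len(nc)) {
    if (region$excluded[j]) next
    rows <- (region$top[j] + 1L):region$bottom[j]
    Ej <- emap$energies[rows, j]
    if (all(is.na(Ej))) next
    res <- tryCatch({
      X <- build_design(Ej, references)
      use <- !is.na(v[rows, j]) & stats::complete.cases(X)
      if (sum(use) <= n_mat) stop("insufficient pixels")
      Xu <- X[use, , drop = FALSE]; yu <- v[rows, j][use]
      cf <- if (nonneg) nnls_fit(Xu, yu) else qr.coef(qr(Xu), yu)
      fit <- as.numeric(Xu %*% cf)
      list(cf = cf, rms = sqrt(mean((yu - fit)^2)),
           dof = sum(use) - n_mat, rows = rows[use], fit = fit)
    }, error = function(e) NULL)
    if (is.null(res)) next
    dens[, j] <- res$cf
    rms[j] <- res$rms
    dof[j] <- res$dof
    if (keep_fitted) fitted[res$rows, j] <- res$fit
  }
  structure(list(projected_density = dens, residual_rms = rms, dof = dof,
                 materials = mats, fitted = fitted,
                 nonneg = nonneg),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  ok <- colSums(!is.na(x$projected_density)) > 0
  cat(sprintf("Fit result: %d materials x %d columns (%d fitted)\n",
              nrow(x$projected_density), ncol(x$projected_density), sum(ok)))
  for (m in x$materials)
    cat(sprintf("  %-20s median rho*t = %.4g g/cm^2\n", m,
                stats::median(x$projected_density[m, ok])))
  cat(sprintf("  median residual RMS  = %.3g\n",
              stats::median(x$residual_rms, na.rm = TRUE)))
  invisible(x)
}

#' Assemble per-projection fits into maps or sinograms
#'
#' Stacks the projected-density rows of successive projections in acquisition
#' order: `"scan"` mode gives a 2-D distribution per material (vertical scan),
#' `"ct"` mode a sinogram per material with recorded angles.
#'
#' @param results List of `fit_result`s, one per projection, in order.
#' @param mode `"scan"` or `"ct"`.
#' @param angles Projection angles in degrees (required for `"ct"`), one per
#'   result.
#' @return A `material_maps` object: named list `maps` of
#'   `n_projections x n_columns` matrices, `materials`, `mode`, `angles`,
#'   `residual_rms`.
#' @export
assemble <- function(results, mode = c("scan", "ct"), angles = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(results) >= 1L)
  mats <- results[[1]]$materials
  ncols <- ncol(results[[1]]$projected_density)
  for (r in results) {
    if (!identical(r$materials, mats))
      stop("inconsistent material lists across projections")
    if (ncol(r$projected_density) != ncols)
      stop("inconsistent column counts across projections")
  }
  if (mode == "ct") {
    if (is.null(angles) || length(angles) != length(results))
      stop("ct mode requires one angle per projection")
  }
  maps <- lapply(mats, function(m)
    do.call(rbind, lapply(results, function(r) r$projected_density[m, ])))
  names(maps) <- mats
  rms <- do.call(rbind, lapply(results, `[[`, "residual_rms"))
  structure(list(materials = mats, maps = maps, mode = mode,
                 angles = angles, residual_rms = rms),
            class = "material_maps")
}

#' @export
print.material_maps <- function(x, ...) {
  d <- dim(x$maps[[1]])
  cat(sprintf("Material %s: %d materials, %d x %d (%s x columns)\n",
              if (x$mode == "ct") "sinograms" else "maps",
              length(x$materials), d[1], d[2],
              if (x$mode == "ct") "angles" else "projections"))
  invisible(x)
}

#' Extract one material's sinogram
#'
#' @param maps A `material_maps` object in `"ct"` mode.
#' @param material Material name.
#' @return A `material_sinogram`: `values` (angles x columns, g/cm^2),
#'   `angles` (degrees), `material`.
#' @export
get_sinogram <- function(maps, material) {
  stopifnot(inherits(maps, "material_maps"))
  if (!identical(maps$mode, "ct"))
    stop("sinograms exist only for ct-mode results")
  if (!material %in% maps$materials)
    stop("unknown material: ", material)
  structure(list(values = maps$maps[[material]], angles = maps$angles,
                 material = material),
            class = "material_sinogram")
}

#' Convert projected density to molar concentration
#'
#' `concentration [mM] = rho_t / (path_length * molar_mass) * 1e6`. With
#' `path_length = 1` cm this also converts a reconstructed volumetric density
#' (g/cm^3) to mM.
#'
#' @param rho_t Projected density, g/cm^2 (or volumetric density g/cm^3 with
#'   unit path length). Vectorized.
#' @param path_length Path length through the solution, cm.
#' @param material [material_spectrum()] carrying `molar_mass`.
#' @return Concentration in mmol/L.
#' @export
to_concentration <- function(rho_t, path_length, material) {
  if (is.null(material$molar_mass))
    stop("material '", material$name, "' has no molar mass")
  if (!is.numeric(path_length) || path_length <= 0)
    stop("path_length must be positive (cm)")
  rho_t / (path_length * material$molar_mass) * 1e6
}
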
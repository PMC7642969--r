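# Reference mass-attenuation spectra: packaged element tables, the mixture
# rule for compounds, externally measured spectra, Gaussian resolution
# blurring and resampling onto a detector column's energy grid.

.spexim_env <- new.env(parent = emptyenv())

#' Construct a reference material spectrum
#'
#' A `material_spectrum` is a named mass-attenuation curve mu/rho(E) used both
#' by the forward simulator and as a component in the least-squares unmixing.
#'
#' @param name Material identifier (used in output file names and fit results).
#' @param energy_grid Strictly ascending photon energies, keV.
#' @param mu_rho Mass attenuation coefficients at `energy_grid`, cm^2/g.
#' @param provenance One of `"tabulated"`, `"measured"`, `"synthetic"`.
#' @param molar_mass Optional molar mass, g/mol (enables conversion of
#'   projected density to molar concentration).
#' @param element_mass_fraction Optional named numeric vector of element mass
#'   fractions (must sum to 1).
#' @return An object of class `material_spectrum`.
#' @export
material_spectrum <- function(name, energy_grid, mu_rho,
                              provenance = c("tabulated", "measured", "synthetic"),
                              molar_mass = NULL, element_mass_fraction = NULL) {
  provenance <- match.arg(provenance)
  energy_grid <- as.numeric(energy_grid)
  mu_rho <- as.numeric(mu_rho)
  if (length(energy_grid) != length(mu_rho) || length(energy_grid) < 2L)
    stop("energy_grid and mu_rho must have equal length >= 2")
  if (any(diff(energy_grid) <= 0))
    stop("energy_grid must be strictly ascending")
  if (any(!is.finite(mu_rho)) || any(mu_rho <= 0))
    stop("mu_rho must be finite and positive")
  if (!is.null(element_mass_fraction) &&
      abs(sum(element_mass_fraction) - 1) > 1e-6)
    stop("element mass fractions must sum to 1")
  structure(list(name = name, energy_grid = energy_grid, mu_rho = mu_rho,
                 provenance = provenance, molar_mass = molar_mass,
                 element_mass_fraction = element_mass_fraction),
            class = "material_spectrum")
}

#' @export
print.material_spectrum <- function(x, ...) {
  cat(sprintf("Material spectrum '%s' (%s): %d knots, %.4f-%.4f keV",
              x$name, x$provenance, length(x$energy_grid),
              min(x$energy_grid), max(x$energy_grid)))
  if (!is.null(x$molar_mass)) cat(sprintf(", M = %.2f g/mol", x$molar_mass))
  cat("\n")
  invisible(x)
}

#' @export
plot.material_spectrum <- function(x, ...) {
  graphics::plot(x$energy_grid, x$mu_rho, type = "l",
                 xlab = "energy (keV)", ylab = expression(mu / rho ~ (cm^2 / g)),
                 main = x$name, ...)
  invisible(x)
}

mu_rho_tables <- function() {
  if (is.null(.spexim_env$mu_rho)) {
    path <- system.file("extdata", "mu_rho_tables.txt", package = "spexim")
    if (!nzchar(path)) path <- file.path("inst", "extdata", "mu_rho_tables.txt")
    tab <- utils::read.table(path, comment.char = "#",
                             col.names = c("element", "branch", "energy", "mu_rho"),
                             stringsAsFactors = FALSE)
    .spexim_env$mu_rho <- split(tab, tab$element)
  }
  .spexim_env$mu_rho
}

#' Tabulated element mass attenuation coefficients
#'
#' Interpolates the packaged element tables (total attenuation:
#' photoelectric + coherent + incoherent) at the requested energies.
#' Interpolation is linear in log-log space within each continuous branch;
#' an absorption-edge discontinuity is never interpolated across (the tables
#' carry two-sided knots at each edge).
#'
#' @param element Element symbol present in the packaged tables
#'   (H, C, N, O, Na, Se).
#' @param energies Photon energies, keV.
#' @return Mass attenuation coefficients, cm^2/g, one per energy.
#' @export
element_mu_rho <- function(element, energies) {
  tabs <- mu_rho_tables()
  if (!element %in% names(tabs))
    stop("element not in packaged tables: ", element,
         " (available: ", paste(names(tabs), collapse = ", "), ")")
  tab <- tabs[[element]]
  if (any(energies < min(tab$energy) | energies > max(tab$energy)))
    stop(sprintf("energy outside table range [%.4f, %.4f] keV for %s",
                 min(tab$energy), max(tab$energy), element))
  out <- numeric(length(energies))
  branches <- split(tab, tab$branch)
  # branch boundaries: assign each query energy to the branch whose energy
  # interval contains it (edges carry two-sided knots, so intervals abut)
  for (b in branches) {
    lo <- min(b$energy); hi <- max(b$energy)
    sel <- energies >= lo & energies <= hi
    if (!any(sel)) next
    out[sel] <- exp(stats::approx(log(b$energy), log(b$mu_rho),
                                  xout = log(energies[sel]), rule = 1)$y)
  }
  out
}

#' List of elements available in the packaged tables
#' @return Character vector of element symbols.
#' @export
available_elements <- function() names(mu_rho_tables())

#' Compound spectrum by the elemental mixture rule
#'
#' mu/rho of a compound is the mass-fraction-weighted sum of its elements'
#' mass attenuation coefficients.
#'
#' @param fractions Named numeric vector of element mass fractions (names are
#'   element symbols); must sum to 1 within 1e-6.
#' @param energies Energy grid for the resulting spectrum, keV.
#' @param name Material name (default: formula-like concatenation).
#' @param molar_mass Optional molar mass, g/mol.
#' @return A [material_spectrum()] with provenance `"tabulated"`.
#' @export
mix_compound <- function(fractions, energies, name = NULL, molar_mass = NULL) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    stop("fractions must be a named vector of element mass fractions")
  if (abs(sum(fractions) - 1) > 1e-6)
    stop("element mass fractions must sum to 1 (got ",
         format(sum(fractions)), ")")
  mu <- numeric(length(energies))
  for (el in names(fractions))
    mu <- mu + fractions[[el]] * element_mu_rho(el, energies)
  if (is.null(name))
    name <- paste0(names(fractions), collapse = "")
  material_spectrum(name, energies, mu, provenance = "tabulated",
                    molar_mass = molar_mass,
                    element_mass_fraction = fractions)
}

#' Water reference spectrum from the element tables
#'
#' Convenience wrapper for the most common matrix material
#' (H 0.1119, O 0.8881 by mass).
#'
#' @param energies Energy grid, keV.
#' @return A [material_spectrum()] named `"water"`.
#' @export
water_spectrum <- function(energies) {
  mix_compound(c(H = 0.1119, O = 0.8881), energies, name = "water",
               molar_mass = 18.015)
}

#' Load an externally measured reference spectrum
#'
#' Reads two-column text (energy keV, mu/rho cm^2/g or normalized absorption);
#' whitespace- or comma-separated, `#` comments. Rows are sorted by energy and
#' exact duplicate rows dropped; duplicate energies with conflicting values
#' are an error.
#'
#' @param source File path, connection, or character vector of lines.
#' @param name Material name for the resulting spectrum.
#' @param molar_mass Optional molar mass, g/mol.
#' @return A [material_spectrum()] with provenance `"measured"`.
#' @export
load_measured_spectrum <- function(source, name, molar_mass = NULL) {
  lines <- if (is.character(source) && length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE)
  else if (inherits(source, "connection")) readLines(source, warn = FALSE)
  else as.character(source)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(gsub(",", " ", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("measured spectrum needs at least 2 rows")
  vals <- lapply(strsplit(lines, "[[:space:]]+"), as.numeric)
  if (any(vapply(vals, length, 1L) < 2L) || any(is.na(unlist(vals))))
    stop("measured spectrum: each row must have two numeric columns")
  E <- vapply(vals, `[`, 0, 1)
  mu <- vapply(vals, `[`, 0, 2)
  o <- order(E)
  E <- E[o]; mu <- mu[o]
  dup <- duplicated(E)
  if (any(dup)) {
    conflict <- vapply(which(dup), function(i)
      any(abs(mu[E == E[i]] - mu[i]) > 0), logical(1))
    if (any(conflict))
      stop("duplicate energies with conflicting values in measured spectrum")
    mu <- mu[!dup]; E <- E[!dup]
  }
  material_spectrum(name, E, mu, provenance = "measured",
                    molar_mass = molar_mass)
}

#' Blur a spectrum to a target energy resolution
#'
#' Convolves mu/rho(E) with a Gaussian of standard deviation `sigma` (keV),
#' emulating the instrument energy resolution so that sharp (externally
#' measured or tabulated) references match what the imaging system sees.
#' Internally the spectrum is resampled to a uniform grid with step
#' `<= sigma/4`, convolved with a normalized discrete kernel (replicated-end
#' padding, so the integral is conserved), and interpolated back onto the
#' original knots.
#'
#' @param spectrum A [material_spectrum()].
#' @param sigma Gaussian standard deviation, keV; `0` returns the input
#'   unchanged.
#' @return A blurred [material_spectrum()] on the same energy grid.
#' @export
blur_spectrum <- function(spectrum, sigma) {
  stopifnot(inherits(spectrum, "material_spectrum"))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("sigma must be a non-negative number (keV)")
  if (sigma == 0) return(spectrum)
  E <- spectrum$energy_grid
  step <- min(sigma / 4, min(diff(E)))
  grid <- seq(min(E), max(E),
              length.out = ceiling((max(E) - min(E)) / step) + 1L)
  step <- grid[2] - grid[1]
  y <- stats::approx(E, spectrum$mu_rho, xout = grid)$y
  half <- ceiling(4 * sigma / step)
  kx <- (-half):half
  kern <- stats::dnorm(kx * step, sd = sigma)
  kern <- kern / sum(kern)
  ypad <- c(rep(y[1], half), y, rep(y[length(y)], half))
  ysm <- stats::filter(ypad, kern, sides = 2)
  ysm <- as.numeric(ysm)[(half + 1):(half + length(y))]
  out <- stats::approx(grid, ysm, xout = E)$y
  material_spectrum(spectrum$name, E, out, provenance = spectrum$provenance,
                    molar_mass = spectrum$molar_mass,
                    element_mass_fraction = spectrum$element_mass_fraction)
}

#' Resample a spectrum onto a detector column's energy grid
#'
#' Linear interpolation of mu/rho at each pixel energy. Pixel energies outside
#' the spectrum's range yield `NA` (masked), which propagates into the fit
#' mask downstream.
#'
#' @param spectrum A [material_spectrum()].
#' @param column_energies Per-pixel energies of one detector column, keV (any
#'   order).
#' @return Numeric vector of mu/rho (cm^2/g) with `NA` for out-of-range
#'   pixels; errors if the entire column is out of range.
#' @export
resample_to_column <- function(spectrum, column_energies) {
  stopifnot(inherits(spectrum, "material_spectrum"))
  out <- stats::approx(spectrum$energy_grid, spectrum$mu_rho,
                       xout = column_energies, rule = 1)$y
  if (all(is.na(out)))
    stop("entire column outside the range of spectrum '", spectrum$name, "'")
  out
}
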
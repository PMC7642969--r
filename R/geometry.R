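# Bragg-law geometry of the bent-Laue energy-dispersive imaging system.
#
# The monochromator focuses a polychromatic fan so that diffraction angle --
# and therefore photon energy -- varies along the vertical detector axis.
# Everything downstream (energy maps, unmixing) rests on the conversions here.

# Single authoritative conversion constant: E[keV] * lambda[Angstrom].
HC_KEV_A <- 12.398420

#' System geometry of the energy-dispersive imaging setup
#'
#' Bundles the monochromator/detector parameters that fix the
#' angle--energy--pixel mapping on the detector.
#'
#' @param asymmetry_angle Laue crystal asymmetry angle, degrees. Retained as
#'   metadata (recorded in the settings record); the pixel-to-energy mapping
#'   itself is fixed by the reflection, edge energy, pixel size and
#'   focus-to-detector distance.
#' @param reflection Integer vector `c(h, k, l)` of Bragg-plane Miller indices.
#' @param edge_energy K-edge energy of the contrast element, keV.
#' @param pixel_size Effective detector pixel pitch, mm.
#' @param focus_to_detector Distance from the diffracted-beam focus to the
#'   detector, mm.
#' @param energy_direction `+1` if energy increases with decreasing row index
#'   (row 0 at the top of the image), `-1` otherwise.
#' @param lattice_constant Cubic lattice constant of the crystal, Angstrom.
#'   Default is silicon, 5.431.
#'
#' @return An object of class `system_geometry`.
#' @seealso [parse_arrangement()], [bragg_angle()], [plane_spacing()]
#' @export
system_geometry <- function(asymmetry_angle = 0,
                            reflection = c(1L, 1L, 1L),
                            edge_energy,
                            pixel_size,
                            focus_to_detector,
                            energy_direction = 1L,
                            lattice_constant = 5.431) {
  reflection <- as.integer(round(reflection))
  if (length(reflection) != 3L || any(!is.finite(reflection)))
    stop("reflection must be three integers (h, k, l)")
  if (all(reflection == 0L))
    stop("reflection (0,0,0) is not a diffracting plane")
  for (nm in c("edge_energy", "pixel_size", "focus_to_detector",
               "lattice_constant")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("non-positive length or energy: ", nm, " must be a positive number")
  }
  if (!energy_direction %in% c(-1, 1))
    stop("energy_direction must be +1 or -1")
  structure(list(
    asymmetry_angle = as.numeric(asymmetry_angle),
    reflection = reflection,
    edge_energy = as.numeric(edge_energy),
    pixel_size = as.numeric(pixel_size),
    focus_to_detector = as.numeric(focus_to_detector),
    energy_direction = as.integer(energy_direction),
    lattice_constant = as.numeric(lattice_constant)
  ), class = "system_geometry")
}

#' @export
print.system_geometry <- function(x, ...) {
  cat("System geometry (bent-Laue energy-dispersive setup)\n")
  cat(sprintf("  reflection          : (%d %d %d), a0 = %.4f A, d = %.5f A\n",
              x$reflection[1], x$reflection[2], x$reflection[3],
              x$lattice_constant, plane_spacing(x)))
  cat(sprintf("  K-edge energy       : %.4f keV  (Bragg angle %.4f deg)\n",
              x$edge_energy, bragg_angle(x$edge_energy, x) * 180 / pi))
  cat(sprintf("  asymmetry angle     : %.3f deg\n", x$asymmetry_angle))
  cat(sprintf("  pixel size          : %.4f mm; focus-to-detector %.1f mm\n",
              x$pixel_size, x$focus_to_detector))
  cat(sprintf("  energy direction    : %+d (energy %s with row index)\n",
              x$energy_direction,
              if (x$energy_direction > 0) "decreases" else "increases"))
  invisible(x)
}

#' Parse an arrangement file into a system geometry
#'
#' The arrangement file is UTF-8 text with one `key = value` pair per line and
#' `#` comments. Required keys: `asymmetry_angle_deg`, `reflection`
#' (comma-separated `h,k,l`), `edge_energy_keV`, `pixel_size_mm`,
#' `focus_to_detector_mm`. Optional: `lattice_constant_A`, `energy_direction`.
#' Unknown keys are tolerated (and ignored).
#'
#' @param source Path to an arrangement file, a connection, or a character
#'   vector of lines.
#' @return A [system_geometry()] object.
#' @export
parse_arrangement <- function(source) {
  lines <- if (is.character(source) && length(source) == 1L &&
               !grepl("=", source, fixed = TRUE) && file.exists(source)) {
    readLines(source, warn = FALSE, encoding = "UTF-8")
  } else if (inherits(source, "connection")) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    key <- trimws(parts[1])
    val <- trimws(paste(parts[-1], collapse = "="))
    kv[[key]] <- val
  }
  required <- c("asymmetry_angle_deg", "reflection", "edge_energy_keV",
                "pixel_size_mm", "focus_to_detector_mm")
  missing <- setdiff(required, names(kv))
  if (length(missing))
    stop("arrangement file: missing key(s): ", paste(missing, collapse = ", "))
  num <- function(key) {
    v <- suppressWarnings(as.numeric(kv[[key]]))
    if (is.na(v)) stop("arrangement file: non-numeric value for ", key)
    v
  }
  refl <- suppressWarnings(as.integer(strsplit(kv[["reflection"]], ",")[[1]]))
  if (length(refl) != 3L || any(is.na(refl)))
    stop("arrangement file: reflection must be three comma-separated integers")
  system_geometry(
    asymmetry_angle = num("asymmetry_angle_deg"),
    reflection = refl,
    edge_energy = num("edge_energy_keV"),
    pixel_size = num("pixel_size_mm"),
    focus_to_detector = num("focus_to_detector_mm"),
    energy_direction = if (is.null(kv[["energy_direction"]])) 1L
                       else as.integer(num("energy_direction")),
    lattice_constant = if (is.null(kv[["lattice_constant_A"]])) 5.431
                       else num("lattice_constant_A")
  )
}

#' Write an arrangement file
#'
#' Inverse of [parse_arrangement()]: serializes a geometry to the `key = value`
#' text format so that parse(write(g)) round-trips every field.
#'
#' @param geometry A [system_geometry()] object.
#' @param path Output file path; if `NULL`, the lines are returned invisibly
#'   without writing.
#' @return Character vector of file lines, invisibly.
#' @export
write_arrangement <- function(geometry, path = NULL) {
  stopifnot(inherits(geometry, "system_geometry"))
  lines <- c(
    "# energy-dispersive imaging system arrangement",
    sprintf("asymmetry_angle_deg = %.10g", geometry$asymmetry_angle),
    sprintf("reflection = %d,%d,%d", geometry$reflection[1],
            geometry$reflection[2], geometry$reflection[3]),
    sprintf("edge_energy_keV = %.10g", geometry$edge_energy),
    sprintf("pixel_size_mm = %.10g", geometry$pixel_size),
    sprintf("focus_to_detector_mm = %.10g", geometry$focus_to_detector),
    sprintf("energy_direction = %d", geometry$energy_direction),
    sprintf("lattice_constant_A = %.10g", geometry$lattice_constant)
  )
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Bragg-plane spacing for a cubic crystal
#'
#' `d = a0 / sqrt(h^2 + k^2 + l^2)` for the geometry's reflection. Only cubic
#' crystals (silicon by default) are supported.
#'
#' @param geometry A [system_geometry()] object.
#' @return Plane spacing in Angstrom.
#' @export
plane_spacing <- function(geometry) {
  stopifnot(inherits(geometry, "system_geometry"))
  h2 <- sum(geometry$reflection^2)
  if (h2 == 0) stop("reflection (0,0,0) has no plane spacing")
  geometry$lattice_constant / sqrt(h2)
}

#' Convert photon energy to Bragg angle and back
#'
#' `bragg_angle()` returns the Bragg diffraction angle for X-rays of the given
#' energy on the geometry's reflection; `bragg_energy()` is its exact inverse.
#' Both use `E = hc / (2 d sin(theta))` with `hc = 12.398420 keV*Angstrom`.
#' Energy is strictly decreasing in angle on (0, pi/2).
#'
#' @param energy Photon energy, keV (vectorized).
#' @param angle Bragg angle, radians (vectorized), in (0, pi/2].
#' @param geometry A [system_geometry()] object.
#' @return `bragg_angle`: radians. `bragg_energy`: keV.
#' @export
bragg_angle <- function(energy, geometry) {
  d <- plane_spacing(geometry)
  s <- HC_KEV_A / (2 * d * energy)
  if (any(!is.finite(s)) || any(energy <= 0))
    stop("energy must be positive and finite")
  if (any(s > 1))
    stop(sprintf(
      "energy below the minimum diffraction energy %.4f keV for this reflection",
      HC_KEV_A / (2 * d)))
  asin(s)
}

#' @rdname bragg_angle
#' @export
bragg_energy <- function(angle, geometry) {
  d <- plane_spacing(geometry)
  if (any(angle <= 0) || any(angle > pi / 2))
    stop("Bragg angle must lie in (0, pi/2]")
  HC_KEV_A / (2 * d * sin(angle))
}
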
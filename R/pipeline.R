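# End-to-end pipeline: load -> average -> normalize -> beam region -> edge ->
# energy map -> resolution -> blurred references -> per-column fits ->
# maps/sinograms -> session archive; plus CT reconstruction and the
# configuration-driven command entry points.

# per-column design matrices and solvers, precomputed once per scan (the
# energy axis does not change between projections)
precompute_designs <- function(emap, region, references) {
  nc <- ncol(emap$energies)
  n_mat <- length(references)
  pre <- vector("list", nc)
  checked <- FALSE
  for (j in seq_len(nc)) {
    if (region$excluded[j]) next
    rows <- (region$top[j] + 1L):region$bottom[j]
    Ej <- emap$energies[rows, j]
    if (all(is.na(Ej))) next
    X <- tryCatch(build_design(Ej, references), error = function(e) NULL)
    if (is.null(X)) next
    use <- stats::complete.cases(X)
    if (sum(use) <= n_mat) next
    Xu <- X[use, , drop = FALSE]
    if (!checked) { check_design(Xu); checked <- TRUE }
    qrX <- qr(Xu)
    pre[[j]] <- list(rows = rows[use], X = Xu, qr = qrX)
  }
  if (!checked) stop("no usable column: check beam region and energy map")
  pre
}

fit_frame_fast <- function(values, pre, n_mat, mat_names, nonneg = FALSE) {
  nc <- length(pre)
  dens <- matrix(NA_real_, n_mat, nc, dimnames = list(mat_names, NULL))
  rms <- rep(NA_real_, nc)
  for (j in seq_len(nc)) {
    p <- pre[[j]]
    if (is.null(p)) next
    y <- values[p$rows, j]
    na <- is.na(y)
    cf <- if (!any(na)) {
      if (nonneg) nnls_fit(p$X, y) else qr.coef(p$qr, y)
    } else {
      if (sum(!na) <= n_mat) next
      Xs <- p$X[!na, , drop = FALSE]
      if (nonneg) nnls_fit(Xs, y[!na]) else qr.coef(qr(Xs), y[!na])
    }
    dens[, j] <- cf
    yy <- if (any(na)) y[!na] else y
    XX <- if (any(na)) p$X[!na, , drop = FALSE] else p$X
    rms[j] <- sqrt(mean((yy - as.numeric(XX %*% cf))^2))
  }
  list(density = dens, rms = rms)
}

#' Analyze an energy-dispersive imaging scan
#'
#' Runs the full analysis chain on in-memory stacks: average the dark and
#' flat stacks, find the useful beam region, normalize and locate the
#' absorption edge, build the per-pixel energy map (one-point from the
#' elemental edge trace, or two-point from the speciation reference's two
#' absorption peaks), estimate the energy resolution and blur the references
#' to match, decompose every projection column-by-column into projected
#' densities, correct beam decay via empty margins (if configured), and
#' assemble maps (`"scan"` mode) or sinograms (`"ct"` mode).
#'
#' @param stacks Named list of [image_stack()]s: `dark`, `flat`,
#'   `edge_elemental` (or `edge`), optionally `edge_speciation`, and `tomo`
#'   (with angles in `"ct"` mode).
#' @param geometry [system_geometry()].
#' @param references List of [material_spectrum()] objects to fit.
#' @param mode `"ct"` (tomo frames are rotation projections) or `"scan"`
#'   (vertical-scan projections).
#' @param calibration `"two_point"` (default; requires `edge_speciation`) or
#'   `"one_point"`.
#' @param anchor_energies The two known feature energies for two-point
#'   calibration, keV. Default `c(12.667, 12.681)` (selenate).
#' @param threshold_fraction,min_height Beam-region tunables (see
#'   [find_beam_region()]).
#' @param smooth_window Edge-detection boxcar window, px.
#' @param margins `c(left, right)` empty-margin widths for decay correction,
#'   or `NULL` to skip.
#' @param nonneg Non-negative fitting. Default `FALSE`.
#' @param blur_references Blur references to the measured resolution before
#'   fitting. Default `TRUE`.
#' @param debias Apply the first-order Poisson log-bias correction during
#'   normalization (see [normalize_attenuation()]). Default `TRUE`.
#' @param out_dir If non-`NULL`, the session archive, map TIFFs and settings
#'   record are written there.
#' @return A `scan_analysis` list: `maps` (`material_maps`), `session`
#'   ([session_archive()]), `resolution`, `trace`, `region`, `emap`,
#'   `decay_offsets`, `settings`.
#' @export
analyze_scan <- function(stacks, geometry, references,
                         mode = c("ct", "scan"),
                         calibration = c("two_point", "one_point"),
                         anchor_energies = c(12.667, 12.681),
                         threshold_fraction = 0.10, smooth_window = 3L,
                         min_height = 8L, margins = NULL, nonneg = FALSE,
                         blur_references = TRUE, debias = TRUE,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  calibration <- match.arg(calibration)
  if (is.null(stacks$dark) || is.null(stacks$flat))
    stop("dark and flat stacks are required")
  edge_stack <- if (!is.null(stacks[["edge_elemental"]]))
    stacks[["edge_elemental"]] else stacks[["edge"]]
  if (is.null(edge_stack)) stop("calibration input missing: no edge stack")
  if (is.null(stacks$tomo)) stop("no tomo stack to analyze")
  dark <- average_stack(stacks$dark)
  flat <- average_stack(stacks$flat)
  region <- find_beam_region(flat, dark, threshold_fraction, min_height)
  edge_att <- normalize_attenuation(average_stack(edge_stack), dark, flat)
  trace <- find_edge(edge_att, region, smooth_window)
  n_rows <- nrow(dark); n_cols <- ncol(dark)
  if (calibration == "two_point") {
    if (is.null(stacks[["edge_speciation"]]))
      stop("calibration input missing: two-point mode needs an",
           " edge_speciation stack")
    spec_att <- normalize_attenuation(
      average_stack(stacks[["edge_speciation"]]), dark, flat)
    peaks <- find_absorption_peaks(spec_att, region,
                                   smooth_window = smooth_window)
    anchors <- anchors_from_peaks(peaks, anchor_energies, geometry)
    emap <- energy_map_two_point(anchors, geometry, n_rows, n_cols)
  } else {
    emap <- energy_map_one_point(trace, geometry, n_rows)
  }
  resolution <- estimate_resolution(trace, emap, geometry)
  refs_used <- if (blur_references)
    lapply(references, blur_spectrum, sigma = resolution$gaussian_sigma)
  else references
  names(refs_used) <- vapply(references, `[[`, "", "name")
  pre <- precompute_designs(emap, region, refs_used)
  n_mat <- length(refs_used)
  mats <- names(refs_used)
  frames <- stacks$tomo$frames
  n_proj <- length(frames)
  offsets <- rep(0, n_proj)
  maps <- lapply(mats, function(m) matrix(NA_real_, n_proj, n_cols))
  names(maps) <- mats
  rms_all <- matrix(NA_real_, n_proj, n_cols)
  last_att <- NULL
  n_flat <- length(stacks$flat$frames)
  for (a in seq_len(n_proj)) {
    att <- normalize_attenuation(frames[[a]], dark, flat, debias = debias,
                                 n_flat_frames = n_flat)
    if (!is.null(margins)) {
      dc <- decay_correct(list(att), margins, region = region)
      att <- dc$corrected[[1]]
      offsets[a] <- dc$offsets
    }
    fr <- fit_frame_fast(att$values, pre, n_mat, mats, nonneg)
    for (m in mats) maps[[m]][a, ] <- fr$density[m, ]
    rms_all[a, ] <- fr$rms
    if (a == n_proj) last_att <- att
  }
  angles <- stacks$tomo$angles
  fit_results <- structure(list(materials = mats, maps = maps, mode = mode,
                                angles = if (mode == "ct") angles,
                                residual_rms = rms_all),
                           class = "material_maps")
  settings <- c(
    sprintf("mode = %s", mode),
    sprintf("calibration = %s", calibration),
    sprintf("anchor_energies_keV = %s",
            paste(anchor_energies, collapse = ",")),
    sprintf("threshold_fraction = %g", threshold_fraction),
    sprintf("smooth_window = %d", as.integer(smooth_window)),
    sprintf("min_region_height = %d", as.integer(min_height)),
    sprintf("margins = %s",
            if (is.null(margins)) "none" else paste(margins, collapse = ",")),
    sprintf("nonneg = %s", nonneg),
    sprintf("blur_references = %s", blur_references),
    sprintf("debias = %s", debias),
    sprintf("materials = %s", paste(mats, collapse = ",")),
    sprintf("resolution_fwhm_keV = %.6g", resolution$fwhm_energy),
    sprintf("n_projections = %d", n_proj))
  session <- session_archive(geometry, energy_map = emap,
                             beam_region = region, edge_trace = trace,
                             references_used = refs_used,
                             attenuation = last_att,
                             fit_results = fit_results,
                             settings_record = settings)
  if (!is.null(out_dir)) save_session(session, out_dir)
  structure(list(maps = fit_results, session = session,
                 resolution = resolution, trace = trace, region = region,
                 emap = emap, decay_offsets = offsets, settings = settings),
            class = "scan_analysis")
}

#' @export
print.scan_analysis <- function(x, ...) {
  cat("Scan analysis\n")
  print(x$maps)
  print(x$resolution)
  invisible(x)
}

#' Reconstruct per-material CT maps from an analysis
#'
#' Finds the rotation center automatically (on the material with the largest
#' total signal) unless given, then reconstructs every material sinogram by
#' filtered back projection. Voxel values are volumetric densities, g/cm^3.
#'
#' @param analysis A `scan_analysis` (ct mode) or `material_maps` in ct mode.
#' @param geometry [system_geometry()] (taken from the analysis session when
#'   available) -- sets the pixel spacing `pixel_size / 10` cm.
#' @param center Rotation-center column (0-based subpixel) or `NULL` for
#'   automatic detection.
#' @param filter_name FBP filter: `"ramp"`, `"shepp-logan"`, `"cosine"`,
#'   `"hamming"`, `"hann"`.
#' @param out_dir If non-`NULL`, one float TIFF per material
#'   (`<material>_recon.tif`) is written there.
#' @return Named list of `recon_map`s.
#' @export
reconstruct_session <- function(analysis, geometry = NULL, center = NULL,
                                filter_name = "ramp", out_dir = NULL) {
  maps <- if (inherits(analysis, "scan_analysis")) analysis$maps
          else analysis
  if (!inherits(maps, "material_maps") || !identical(maps$mode, "ct"))
    stop("missing sinograms: reconstruction needs ct-mode fit results")
  if (is.null(geometry) && inherits(analysis, "scan_analysis"))
    geometry <- analysis$session$geometry
  spacing <- if (is.null(geometry)) 1 else geometry$pixel_size / 10
  if (is.null(center)) {
    tot <- vapply(maps$materials, function(m)
      sum(abs(maps$maps[[m]]), na.rm = TRUE), 0)
    center <- find_center(get_sinogram(maps, maps$materials[which.max(tot)]))
  }
  recons <- lapply(maps$materials, function(m)
    reconstruct_fbp(get_sinogram(maps, m), center = center,
                    filter_name = filter_name, pixel_spacing = spacing))
  names(recons) <- maps$materials
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (m in maps$materials)
      write_float_tiff(recons[[m]]$values, file.path(out_dir, paste0(
        gsub("[^A-Za-z0-9_.-]", "_", m), "_recon.tif")))
  }
  recons
}

#' Fit-diagnostic panel for one detector column
#'
#' Plots the measured attenuation spectrum of a column against the fitted
#' model and each reference's weighted contribution.
#'
#' @param attenuation `attenuation_image` of one projection.
#' @param emap Energy map.
#' @param region Beam region.
#' @param references Reference spectra used in the fit.
#' @param column Column index (1-based).
#' @param nonneg Non-negative fit. Default `FALSE`.
#' @param path Optional PNG output path.
#' @return The per-column fit (from [fit_column()]), invisibly.
#' @export
plot_fit_diagnostics <- function(attenuation, emap, region, references,
                                 column, nonneg = FALSE, path = NULL) {
  rows <- (region$top[column] + 1L):region$bottom[column]
  E <- emap$energies[rows, column]
  y <- attenuation$values[rows, column]
  fit <- fit_column(y, E, references, nonneg = nonneg)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(E, y, pch = 16, cex = 0.5, xlab = "energy (keV)",
                 ylab = expression(-ln(T)),
                 main = sprintf("column %d fit", column))
  graphics::lines(E, fit$fitted, col = "red", lwd = 2)
  cols <- seq_along(references) + 2
  for (i in seq_along(references)) {
    mu <- resample_to_column(references[[i]], E)
    graphics::lines(E, mu * fit$coefficients[i], col = cols[i], lty = 2)
  }
  graphics::legend("topleft", bty = "n",
                   legend = c("measured", "fitted",
                              sprintf("%s (%.3g g/cm2)",
                                      vapply(references, `[[`, "", "name"),
                                      fit$coefficients)),
                   col = c("black", "red", cols),
                   lty = c(NA, 1, rep(2, length(references))),
                   pch = c(16, NA, rep(NA, length(references))))
  invisible(fit)
}

# ---------------------------------------------------------------------------
# Configuration-driven command entry points (the CLI wraps these).

read_run_config <- function(source) {
  lines <- if (is.character(source) && length(source) == 1L &&
               file.exists(source)) readLines(source, warn = FALSE)
           else as.character(source)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) < 2L) next
    cfg[[trimws(parts[1])]] <- trimws(paste(parts[-1], collapse = "="))
  }
  cfg
}

resolve_references <- function(spec) {
  names <- strsplit(spec, ",")[[1]]
  lapply(trimws(names), function(nm) {
    if (file.exists(nm)) load_measured_spectrum(nm, name = basename(nm))
    else species_spectrum(nm)
  })
}

#' Run the analysis pipeline from a configuration
#'
#' Configuration is a flat `key = value` file (or named list). Keys:
#' `arrangement` (path), `dark`, `flat`, `edge_elemental`,
#' `edge_speciation`, `tomo` (directories or comma-separated files),
#' `materials` (comma-separated species names or spectrum file paths),
#' `mode` (`scan`/`ct`), `calibration` (`one_point`/`two_point`),
#' `anchor_energies` (comma-separated keV), `threshold_fraction`,
#' `smooth_window`, `margins` (comma-separated left,right), `nonneg`,
#' `angles` (comma-separated degrees for ct), `out_dir`.
#'
#' @param config Path to a config file, character vector of lines, or a
#'   named list.
#' @return A `scan_analysis`, invisibly; the session archive is written to
#'   `out_dir`.
#' @export
cmd_analyze <- function(config) {
  cfg <- if (is.list(config)) config else read_run_config(config)
  need <- function(key) {
    if (is.null(cfg[[key]])) stop("config missing required key: ", key)
    cfg[[key]]
  }
  geometry <- parse_arrangement(need("arrangement"))
  split_paths <- function(v) {
    p <- trimws(strsplit(v, ",")[[1]])
    if (length(p) == 1L && dir.exists(p)) p else p
  }
  stacks <- list(
    dark = load_stack(split_paths(need("dark")), "dark"),
    flat = load_stack(split_paths(need("flat")), "flat"))
  if (is.null(cfg$edge_elemental))
    stop("calibration input missing: edge_elemental")
  stacks$edge_elemental <- load_stack(split_paths(cfg$edge_elemental), "edge")
  if (!is.null(cfg$edge_speciation))
    stacks$edge_speciation <- load_stack(split_paths(cfg$edge_speciation),
                                         "edge")
  angles <- if (!is.null(cfg$angles))
    as.numeric(strsplit(cfg$angles, ",")[[1]])
  stacks$tomo <- load_stack(split_paths(need("tomo")), "tomo",
                            angles = angles)
  mode <- if (is.null(cfg$mode)) "ct" else cfg$mode
  res <- analyze_scan(
    stacks, geometry,
    references = resolve_references(need("materials")),
    mode = mode,
    calibration = if (is.null(cfg$calibration)) "two_point"
                  else cfg$calibration,
    anchor_energies = if (is.null(cfg$anchor_energies)) c(12.667, 12.681)
                      else as.numeric(strsplit(cfg$anchor_energies, ",")[[1]]),
    threshold_fraction = if (is.null(cfg$threshold_fraction)) 0.10
                         else as.numeric(cfg$threshold_fraction),
    smooth_window = if (is.null(cfg$smooth_window)) 3L
                    else as.integer(cfg$smooth_window),
    margins = if (!is.null(cfg$margins))
      as.integer(strsplit(cfg$margins, ",")[[1]]),
    nonneg = !is.null(cfg$nonneg) && tolower(cfg$nonneg) %in%
      c("true", "1", "yes"),
    out_dir = need("out_dir"))
  invisible(res)
}

#' Reconstruct CT maps from a saved session
#'
#' Config keys: `session_dir` (directory holding `session.xsar`), `out_dir`,
#' optional `center` (`auto` or a number) and `filter` (default `ramp`).
#'
#' @param config Path, lines, or named list (see [cmd_analyze()]).
#' @return Named list of `recon_map`s, invisibly.
#' @export
cmd_reconstruct <- function(config) {
  cfg <- if (is.list(config)) config else read_run_config(config)
  if (is.null(cfg$session_dir)) stop("config missing required key: session_dir")
  session <- load_session(cfg$session_dir)
  if (is.null(session$fit_results))
    stop("missing sinograms: the session has no fit results")
  center <- if (is.null(cfg$center) || identical(cfg$center, "auto")) NULL
            else as.numeric(cfg$center)
  recons <- reconstruct_session(session$fit_results,
                                geometry = session$geometry,
                                center = center,
                                filter_name = if (is.null(cfg$filter)) "ramp"
                                              else cfg$filter,
                                out_dir = if (is.null(cfg$out_dir))
                                  cfg$session_dir else cfg$out_dir)
  invisible(recons)
}

#' Simulate a scan and write it to disk as detector files
#'
#' Writes 16-bit TIFF stacks (dark/, flat/, edge_elemental/,
#' edge_speciation/, tomo/), an arrangement file, an `angles.txt`, and the
#' ground truth as a keyed archive (`truth.xsar`), so the analysis commands
#' consume simulated data exactly as real data.
#'
#' @param out_dir Output directory.
#' @param kind Phantom kind (see [make_demo_phantom()]), or `NULL` for an
#'   empty sample.
#' @param ... Passed to [simulate_scan()].
#' @return The simulation (list of `stacks` and `truth`), invisibly.
#' @export
simulate_to_dir <- function(out_dir, kind = "three_species_disks", ...) {
  phantom <- if (is.null(kind)) NULL else make_demo_phantom(kind)
  sim <- simulate_scan(phantom, ...)
  for (role in names(sim$stacks)) {
    d <- file.path(out_dir, role)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    fr <- sim$stacks[[role]]$frames
    for (i in seq_along(fr))
      write_count_tiff(pmin(fr[[i]], 65535), file.path(d, sprintf(
        "%s_%04d.tif", role, i)))
  }
  write_arrangement(sim$truth$geometry, file.path(out_dir, "arrangement.txt"))
  writeLines(format(sim$truth$angles, digits = 10),
             file.path(out_dir, "angles.txt"))
  tr <- sim$truth
  write_archive(list(
    energy_map = tr$emap$energies,
    edge_rows = tr$edge_rows,
    flux_factors = tr$flux_factors,
    rho_t = if (!is.null(tr$rho_t)) tr$rho_t,
    sigma_E = tr$sigma_E,
    angles = tr$angles), file.path(out_dir, "truth.xsar"))
  invisible(sim)
}
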
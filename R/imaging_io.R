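# Detector image I/O: role-tagged stacks of 2-D count images, averaging,
# float TIFF output, the keyed binary session archive and the settings record.

#' Role-tagged stack of detector images
#'
#' @param frames List of 2-D numeric matrices (counts), all the same shape.
#' @param role One of `"dark"`, `"flat"`, `"edge"`, `"tomo"`.
#' @param slice_index Optional integer slice id (multi-slice CT grouping).
#' @param angles Optional numeric vector of projection angles in degrees, one
#'   per frame (tomo stacks).
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, role = c("dark", "flat", "edge", "tomo"),
                        slice_index = NULL, angles = NULL) {
  role <- match.arg(role)
  if (!is.list(frames) || length(frames) == 0L)
    stop("frames must be a non-empty list of matrices")
  dims <- lapply(frames, dim)
  if (any(vapply(dims, is.null, TRUE)))
    stop("every frame must be a 2-D matrix")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("shape mismatch between frames in one stack")
  for (f in frames)
    if (any(!is.finite(f)) || any(f < 0))
      stop("counts must be finite and non-negative")
  if (!is.null(angles) && length(angles) != length(frames))
    stop("angles must have one entry per frame")
  structure(list(frames = frames, role = role, slice_index = slice_index,
                 angles = angles),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Image stack: role '%s', %d frame(s) of %d x %d\n",
              x$role, length(x$frames), d[1], d[2]))
  invisible(x)
}

#' Default number of frames loaded per role
#'
#' Dark and flat correction stacks are limited to ten frames by default and
#' averaged; edge and tomo stacks load every file given.
#'
#' @param role One of `"dark"`, `"flat"`, `"edge"`, `"tomo"`.
#' @return Frame limit (possibly `Inf`).
#' @export
default_frame_limit <- function(role = c("dark", "flat", "edge", "tomo")) {
  role <- match.arg(role)
  if (role %in% c("dark", "flat")) 10 else Inf
}

#' Load a stack of detector TIFF images
#'
#' Files are loaded in filename sort order. For dark and flat roles at most
#' `n_limit` frames (default ten) are read; edge and tomo load all files.
#' 16-bit integer TIFFs are returned as raw counts; float TIFFs as stored.
#'
#' @param paths Character vector of TIFF file paths, or a directory (all
#'   `*.tif`/`*.tiff` inside are used).
#' @param role Stack role tag.
#' @param n_limit Maximum number of frames to load; `NULL` uses
#'   [default_frame_limit()] for the role.
#' @param slice_pattern Optional regular expression with one capture group
#'   extracting a slice id from each filename; when given, tomo frames are
#'   grouped by slice and a list of `image_stack`s (one per slice, ordered by
#'   id) is returned.
#' @param angles Optional per-frame projection angles, degrees.
#' @return An [image_stack()] (or a list of them when `slice_pattern` groups
#'   tomo frames).
#' @export
load_stack <- function(paths, role = c("dark", "flat", "edge", "tomo"),
                       n_limit = NULL, slice_pattern = NULL, angles = NULL) {
  role <- match.arg(role)
  if (length(paths) == 1L && dir.exists(paths))
    paths <- list.files(paths, pattern = "\\.tiff?$", full.names = TRUE,
                        ignore.case = TRUE)
  if (length(paths) == 0L) stop("empty file list for role '", role, "'")
  paths <- paths[order(basename(paths))]
  if (is.null(n_limit)) n_limit <- default_frame_limit(role)
  if (!is.null(slice_pattern) && role == "tomo") {
    ids <- sub(paste0(".*", slice_pattern, ".*"), "\\1", basename(paths))
    groups <- split(paths, ids)
    return(lapply(groups[order(names(groups))], function(p)
      load_stack(p, role = "tomo", n_limit = n_limit)))
  }
  if (is.finite(n_limit) && length(paths) > n_limit)
    paths <- paths[seq_len(n_limit)]
  frames <- lapply(paths, function(p) {
    img <- tryCatch(tiff::readTIFF(p, as.is = TRUE),
                    error = function(e) tryCatch(tiff::readTIFF(p),
                                                 error = function(e2)
                      stop("unreadable image file: ", p)))
    if (length(dim(img)) == 3L && dim(img)[3] == 1L) img <- img[, , 1]
    storage.mode(img) <- "double"
    img
  })
  image_stack(frames, role = role, angles = angles)
}

#' Average the frames of a stack
#'
#' Element-wise arithmetic mean over frames, returned as a double matrix.
#'
#' @param stack An [image_stack()] with at least one frame.
#' @return 2-D numeric matrix.
#' @export
average_stack <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) == 0L) stop("empty stack")
  Reduce(`+`, stack$frames) / length(stack$frames)
}

# ---------------------------------------------------------------------------
# 32-bit float TIFF output (r-tiff only writes [0,1]-scaled integer samples).
# Single strip, uncompressed, little-endian, SampleFormat = IEEE float;
# readable by libtiff (tiff::readTIFF) and any imaging tool.

#' Write a 2-D array as a 32-bit float grayscale TIFF
#'
#' @param x Numeric matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_float_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  nr <- nrow(x); nc <- ncol(x)
  con <- file(path, "wb"); on.exit(close(con))
  w2 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w4 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); w2(42L); w4(8L)
  tags <- list(
    c(256L, 3L, 1L, nc),         # ImageWidth
    c(257L, 3L, 1L, nr),         # ImageLength
    c(258L, 3L, 1L, 32L),        # BitsPerSample
    c(259L, 3L, 1L, 1L),         # no compression
    c(262L, 3L, 1L, 1L),         # BlackIsZero
    c(273L, 4L, 1L, 0L),         # StripOffsets, patched below
    c(277L, 3L, 1L, 1L),         # SamplesPerPixel
    c(278L, 3L, 1L, nr),         # RowsPerStrip
    c(279L, 4L, 1L, 4L * nr * nc), # StripByteCounts
    c(339L, 3L, 1L, 3L))         # SampleFormat: IEEE float
  n <- length(tags)
  tags[[6]][4] <- 8L + 2L + n * 12L + 4L
  w2(n)
  for (tg in tags) { w2(tg[1]); w2(tg[2]); w4(tg[3]); w4(tg[4]) }
  w4(0L)
  writeBin(as.vector(t(x)), con, size = 4, endian = "little")
  invisible(path)
}

#' Write a count image as a 16-bit integer grayscale TIFF
#'
#' Values must lie in `[0, 65535]`; they are rounded to integers.
#'
#' @param x Numeric matrix of counts.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_count_tiff <- function(x, path) {
  stopifnot(is.matrix(x))
  x <- round(x)
  if (any(x < 0) || any(x > 65535))
    stop("counts outside the 16-bit range [0, 65535]")
  tiff::writeTIFF(x / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Keyed-array archive ("XSAR"): one self-describing binary file holding named
# double/integer arrays and strings. Layout:
#   bytes 0-7   magic "XSARCH01"
#   bytes 8-11  uint32 little-endian header length L
#   bytes 12..  UTF-8 JSON header: list of {name, type, dim, offset, size}
#               (offset relative to payload start, size in bytes;
#                type in {"double","integer","character"})
#   payload     raw little-endian IEEE-754 doubles / int32 / UTF-8 bytes
# Doubles round-trip bit-exactly.

#' Write named arrays to a keyed binary archive
#'
#' Stores a flat named list of numeric/integer arrays (dimensions preserved)
#' and character scalars in a single self-describing file. Doubles round-trip
#' bit-exactly. See the package vignette for the byte-level layout.
#'
#' @param entries Named list of numeric arrays, integer arrays, or character
#'   scalars. `NULL` entries are skipped.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_archive <- function(entries, path) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("entries must be a fully named list")
  entries <- entries[!vapply(entries, is.null, TRUE)]
  header <- list(); blobs <- list(); off <- 0L
  for (nm in names(entries)) {
    x <- entries[[nm]]
    if (is.character(x)) {
      raw <- charToRaw(paste(x, collapse = "\n"))
      type <- "character"; dm <- length(x)
    } else if (is.integer(x) || is.logical(x)) {
      raw <- writeBin(as.integer(x), raw(), size = 4, endian = "little")
      type <- "integer"; dm <- if (is.null(dim(x))) length(x) else dim(x)
    } else if (is.numeric(x)) {
      raw <- writeBin(as.vector(as.double(x)), raw(), size = 8,
                      endian = "little")
      type <- "double"; dm <- if (is.null(dim(x))) length(x) else dim(x)
    } else stop("unsupported entry type for '", nm, "'")
    header[[length(header) + 1L]] <- list(name = nm, type = type,
                                          dim = as.integer(dm),
                                          offset = off, size = length(raw))
    blobs[[length(blobs) + 1L]] <- raw
    off <- off + length(raw)
  }
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw("XSARCH01"), con)
  writeBin(length(hjson), con, size = 4, endian = "little")
  writeBin(hjson, con)
  for (b in blobs) writeBin(b, con)
  invisible(path)
}

#' Read a keyed binary archive written by [write_archive()]
#'
#' @param path Archive file path.
#' @return Named list of arrays/strings with original dimensions.
#' @export
read_archive <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- rawToChar(readBin(con, raw(), 8))
  if (magic != "XSARCH01") stop("not an XSAR archive: ", path)
  hlen <- readBin(con, integer(), 1, size = 4, endian = "little")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, raw(), hlen)),
                               simplifyVector = FALSE)
  payload <- readBin(con, raw(), n = file.info(path)$size)
  out <- list()
  for (h in header) {
    raw <- payload[(h$offset + 1L):(h$offset + h$size)]
    dm <- as.integer(unlist(h$dim))
    x <- switch(h$type,
      character = strsplit(rawToChar(raw), "\n", fixed = TRUE)[[1]],
      integer = readBin(raw, integer(), n = h$size / 4, size = 4,
                        endian = "little"),
      double = readBin(raw, double(), n = h$size / 8, size = 8,
                       endian = "little"),
      stop("unknown entry type ", h$type))
    if (h$type != "character" && length(dm) > 1L) dim(x) <- dm
    if (h$type == "character" && length(x) == 0L) x <- ""
    out[[h$name]] <- x
  }
  out
}

# ---------------------------------------------------------------------------
# Session archive: every mid-way result of one analysis run, so that in-depth
# evaluation does not require re-running the pipeline.

#' Bundle the results of an analysis run
#'
#' @param geometry [system_geometry()] used.
#' @param energy_map Optional `energy_map` object.
#' @param beam_region Optional `beam_region` object.
#' @param edge_trace Optional `edge_trace` object.
#' @param references_used Optional list of [material_spectrum()] objects.
#' @param attenuation Optional `attenuation_image` (flat/dark-corrected data).
#' @param fit_results Optional `material_maps` object (per-material 2-D maps
#'   or sinograms).
#' @param settings_record Character vector: the plain-text record of every
#'   tunable used.
#' @return An object of class `session_archive`.
#' @export
session_archive <- function(geometry, energy_map = NULL, beam_region = NULL,
                            edge_trace = NULL, references_used = NULL,
                            attenuation = NULL, fit_results = NULL,
                            settings_record = character()) {
  stopifnot(inherits(geometry, "system_geometry"))
  structure(list(geometry = geometry, energy_map = energy_map,
                 beam_region = beam_region, edge_trace = edge_trace,
                 references_used = references_used, attenuation = attenuation,
                 fit_results = fit_results,
                 settings_record = settings_record),
            class = "session_archive")
}

#' Save a session archive to disk
#'
#' Writes one keyed binary archive (`session.xsar`), one 32-bit float TIFF per
#' material map in `fit_results`, and a plain-text settings record
#' (`settings.txt`). A reloaded archive reproduces all arrays bit-exactly.
#'
#' @param archive A [session_archive()].
#' @param out_dir Output directory (created if needed).
#' @return Character vector of paths written, invisibly.
#' @export
save_session <- function(archive, out_dir) {
  stopifnot(inherits(archive, "session_archive"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  g <- archive$geometry
  entries <- list(
    "geometry/numeric" = c(asymmetry_angle = g$asymmetry_angle,
                           edge_energy = g$edge_energy,
                           pixel_size = g$pixel_size,
                           focus_to_detector = g$focus_to_detector,
                           lattice_constant = g$lattice_constant),
    "geometry/reflection" = g$reflection,
    "geometry/energy_direction" = as.integer(g$energy_direction),
    "settings" = if (length(archive$settings_record))
      archive$settings_record else NULL
  )
  if (!is.null(archive$energy_map))
    entries[["energy_map"]] <- archive$energy_map$energies
  if (!is.null(archive$beam_region)) {
    entries[["beam_region/top"]] <- as.integer(archive$beam_region$top)
    entries[["beam_region/bottom"]] <- as.integer(archive$beam_region$bottom)
    entries[["beam_region/excluded"]] <- as.integer(archive$beam_region$excluded)
  }
  if (!is.null(archive$edge_trace)) {
    entries[["edge_trace/row"]] <- archive$edge_trace$row
    entries[["edge_trace/fwhm"]] <- archive$edge_trace$fwhm
    entries[["edge_trace/valid"]] <- as.integer(archive$edge_trace$valid)
  }
  if (!is.null(archive$attenuation)) {
    entries[["attenuation/values"]] <- archive$attenuation$values
    entries[["attenuation/mask"]] <- array(as.integer(archive$attenuation$mask),
                                           dim(archive$attenuation$mask))
  }
  refs <- archive$references_used
  if (!is.null(refs)) {
    entries[["references/names"]] <- vapply(refs, `[[`, "", "name")
    for (r in refs) {
      entries[[paste0("references/", r$name, "/energy")]] <- r$energy_grid
      entries[[paste0("references/", r$name, "/mu_rho")]] <- r$mu_rho
      entries[[paste0("references/", r$name, "/provenance")]] <- r$provenance
      if (!is.null(r$molar_mass))
        entries[[paste0("references/", r$name, "/molar_mass")]] <- r$molar_mass
    }
  }
  paths <- character()
  fr <- archive$fit_results
  if (!is.null(fr)) {
    entries[["fit/materials"]] <- fr$materials
    entries[["fit/mode"]] <- fr$mode
    if (!is.null(fr$angles)) entries[["fit/angles"]] <- fr$angles
    if (!is.null(fr$residual_rms))
      entries[["fit/residual_rms"]] <- fr$residual_rms
    for (m in fr$materials) {
      entries[[paste0("fit/map/", m)]] <- fr$maps[[m]]
      tif <- file.path(out_dir, paste0(
        gsub("[^A-Za-z0-9_.-]", "_", m),
        if (identical(fr$mode, "ct")) "_sino.tif" else "_map.tif"))
      write_float_tiff(fr$maps[[m]], tif)
      paths <- c(paths, tif)
    }
  } else {
    warning("session has no fit results; no map TIFFs written")
  }
  arc <- file.path(out_dir, "session.xsar")
  write_archive(entries, arc)
  set <- file.path(out_dir, "settings.txt")
  writeLines(c(write_arrangement(g),
               if (length(archive$settings_record)) archive$settings_record),
             set)
  invisible(c(arc, paths, set))
}

#' Reload a session archive saved by [save_session()]
#'
#' @param out_dir Directory containing `session.xsar`.
#' @return A [session_archive()] with all arrays restored bit-exactly.
#' @export
load_session <- function(out_dir) {
  e <- read_archive(file.path(out_dir, "session.xsar"))
  gn <- e[["geometry/numeric"]]
  names(gn) <- c("asymmetry_angle", "edge_energy", "pixel_size",
                 "focus_to_detector", "lattice_constant")
  g <- system_geometry(asymmetry_angle = gn["asymmetry_angle"],
                       reflection = e[["geometry/reflection"]],
                       edge_energy = gn[["edge_energy"]],
                       pixel_size = gn[["pixel_size"]],
                       focus_to_detector = gn[["focus_to_detector"]],
                       energy_direction = e[["geometry/energy_direction"]],
                       lattice_constant = gn[["lattice_constant"]])
  emap <- if (!is.null(e[["energy_map"]]))
    structure(list(energies = e[["energy_map"]]), class = "energy_map")
  region <- if (!is.null(e[["beam_region/top"]]))
    structure(list(top = e[["beam_region/top"]],
                   bottom = e[["beam_region/bottom"]],
                   excluded = as.logical(e[["beam_region/excluded"]])),
              class = "beam_region")
  trace <- if (!is.null(e[["edge_trace/row"]]))
    structure(list(row = e[["edge_trace/row"]], fwhm = e[["edge_trace/fwhm"]],
                   valid = as.logical(e[["edge_trace/valid"]])),
              class = "edge_trace")
  atten <- if (!is.null(e[["attenuation/values"]]))
    structure(list(values = e[["attenuation/values"]],
                   mask = array(as.logical(e[["attenuation/mask"]]),
                                dim(e[["attenuation/mask"]]))),
              class = "attenuation_image")
  refs <- NULL
  if (!is.null(e[["references/names"]])) {
    refs <- lapply(e[["references/names"]], function(nm) {
      material_spectrum(nm,
        e[[paste0("references/", nm, "/energy")]],
        e[[paste0("references/", nm, "/mu_rho")]],
        provenance = e[[paste0("references/", nm, "/provenance")]],
        molar_mass = e[[paste0("references/", nm, "/molar_mass")]])
    })
  }
  fit <- NULL
  if (!is.null(e[["fit/materials"]])) {
    mats <- e[["fit/materials"]]
    maps <- lapply(mats, function(m) e[[paste0("fit/map/", m)]])
    names(maps) <- mats
    fit <- structure(list(materials = mats, maps = maps,
                          mode = e[["fit/mode"]],
                          angles = e[["fit/angles"]],
                          residual_rms = e[["fit/residual_rms"]]),
                     class = "material_maps")
  }
  session_archive(g, energy_map = emap, beam_region = region,
                  edge_trace = trace, references_used = refs,
                  attenuation = atten, fit_results = fit,
                  settings_record = if (is.null(e[["settings"]])) character()
                                    else e[["settings"]])
}
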